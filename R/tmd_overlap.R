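# Intersection of per-residue degron probabilities with transmembrane
# segment annotations, and the high- vs low-probability TMD contrasts.

#' Read transmembrane-segment annotations
#'
#' Accepts either TMHMM long-format output (whitespace-delimited lines
#' `<id> <method> TMhelix <start> <end>`; non-`TMhelix` topology lines and
#' `#` comments are ignored) or a simple TSV with header columns
#' `protein_id`, `start`, `end`. Intervals are 1-based inclusive in both
#' dialects; the dialect detected is recorded as an attribute.
#'
#' @param path Annotation file.
#' @return Tibble (`protein_id`, `start`, `end`), sorted within protein.
#' @export
read_tm_annotations <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty annotation file: ", path, call. = FALSE)
  header <- strsplit(trimws(lines[1]), "\t|\\s+")[[1]]
  if (all(c("protein_id", "start", "end") %in% header)) {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    out <- tibble::tibble(protein_id = as.character(tab$protein_id),
                          start = as.integer(tab$start),
                          end = as.integer(tab$end))
    dialect <- "tsv"
  } else {
    body <- lines[!startsWith(trimws(lines), "#")]
    fields <- strsplit(trimws(body), "\\s+")
    keep <- vapply(fields, function(f)
      length(f) >= 5 && f[3] == "TMhelix", logical(1))
    fields <- fields[keep]
    out <- tibble::tibble(
      protein_id = vapply(fields, `[`, character(1), 1),
      start = as.integer(vapply(fields, `[`, character(1), 4)),
      end = as.integer(vapply(fields, `[`, character(1), 5)))
    dialect <- "tmhmm"
  }
  bad <- which(is.na(out$start) | is.na(out$end) | out$end < out$start)
  if (length(bad))
    stop(sprintf("malformed interval (end < start or non-numeric) for %s",
                 paste(out$protein_id[bad], collapse = ", ")), call. = FALSE)
  out <- out[order(out$protein_id, out$start), ]
  for (id in unique(out$protein_id)) {
    seg <- out[out$protein_id == id, ]
    if (nrow(seg) > 1L && any(seg$start[-1] <= seg$end[-nrow(seg)]))
      stop("overlapping TM segments for protein ", id, call. = FALSE)
  }
  attr(out, "dialect") <- dialect
  out
}

.tm_residues <- function(tm, id) {
  seg <- tm[tm$protein_id == id, ]
  if (!nrow(seg)) return(integer(0))
  unlist(Map(seq.int, seg$start, seg$end))
}

#' Per-residue intersection of degron calls and TM segments
#'
#' Over residues with a defined degron probability, partitions each residue
#' into degron-only, TMD-only, or both (degron call at probability >=
#' `cutoff` that also lies in a TM segment). Segment/region-level Venn
#' counts are reported alongside the residue counts (a region or segment
#' counts as overlapping if it shares at least one residue with the other
#' class).
#'
#' @param profiles Named list of `degron_profile`s (names = protein ids, or
#'   taken from each profile's `protein_id`).
#' @param tm TM annotation tibble from [read_tm_annotations()].
#' @param cutoff Degron probability cutoff (default 0.85, inclusive).
#' @return List with `residues` (degron_only, tmd_only, both),
#'   `segments` (degron regions only / TM segments only / overlapping
#'   counts), and `n_proteins` used.
#' @export
residue_intersection <- function(profiles, tm, cutoff = 0.85) {
  profiles <- .name_profiles(profiles)
  shared <- intersect(names(profiles), unique(tm$protein_id))
  missing <- setdiff(union(names(profiles), unique(tm$protein_id)), shared)
  if (length(missing))
    message("proteins present on one side only: ",
            paste(missing, collapse = ", "))
  res <- c(degron_only = 0L, tmd_only = 0L, both = 0L)
  seg <- c(region_only = 0L, segment_only = 0L, overlapping_regions = 0L,
           overlapping_segments = 0L)
  for (id in names(profiles)) {
    pr <- profiles[[id]]
    defined <- which(!is.na(pr$probability))
    deg_res <- defined[pr$probability[defined] >= cutoff]
    tm_res <- intersect(.tm_residues(tm, id), defined)
    both_res <- intersect(deg_res, tm_res)
    res["degron_only"] <- res["degron_only"] + length(setdiff(deg_res, tm_res))
    res["tmd_only"] <- res["tmd_only"] + length(setdiff(tm_res, deg_res))
    res["both"] <- res["both"] + length(both_res)
    # region/segment-level counts
    regions <- pr$regions
    reg_hit <- if (nrow(regions))
      vapply(seq_len(nrow(regions)), function(k)
        any(seq.int(regions$start[k], regions$end[k]) %in% tm_res),
        logical(1))
    else logical(0)
    segs <- tm[tm$protein_id == id, ]
    seg_hit <- if (nrow(segs))
      vapply(seq_len(nrow(segs)), function(k)
        any(seq.int(segs$start[k], segs$end[k]) %in% deg_res), logical(1))
    else logical(0)
    seg["region_only"] <- seg["region_only"] + sum(!reg_hit)
    seg["overlapping_regions"] <- seg["overlapping_regions"] + sum(reg_hit)
    seg["segment_only"] <- seg["segment_only"] + sum(!seg_hit)
    seg["overlapping_segments"] <- seg["overlapping_segments"] + sum(seg_hit)
  }
  list(residues = res, segments = seg, n_proteins = length(profiles),
       cutoff = cutoff)
}

.name_profiles <- function(profiles) {
  if (inherits(profiles, "degron_profile")) profiles <- list(profiles)
  if (is.null(names(profiles)) || any(!nzchar(names(profiles))))
    names(profiles) <- vapply(profiles, function(p) p$protein_id,
                              character(1))
  profiles
}

#' Classify TM segments by degron probability
#'
#' Summarizes each TM segment by a statistic of the defined per-residue
#' degron probabilities it covers (default the maximum: a degron call
#' anywhere in the segment makes the whole segment act as a degron) and
#' splits segments into a high group (statistic >= `cutoff`) and a low
#' group. Segments with no residue in the defined range (too close to a
#' terminus) are excluded with a message.
#'
#' @param profiles Named list of `degron_profile`s.
#' @param tm TM annotation tibble.
#' @param cutoff Probability cutoff (default 0.85).
#' @param stat `"max"` (default) or `"mean"` segment summary.
#' @return Tibble (`protein_id`, `start`, `end`, `prob`, `group`
#'   high/low).
#' @export
segment_degron_fraction <- function(profiles, tm, cutoff = 0.85,
                                    stat = c("max", "mean")) {
  stat <- match.arg(stat)
  profiles <- .name_profiles(profiles)
  tm <- tm[tm$protein_id %in% names(profiles), ]
  prob <- numeric(nrow(tm))
  keep <- logical(nrow(tm))
  for (k in seq_len(nrow(tm))) {
    pr <- profiles[[tm$protein_id[k]]]
    idx <- seq.int(tm$start[k], min(tm$end[k], pr$length))
    vals <- pr$probability[idx]
    vals <- vals[!is.na(vals)]
    keep[k] <- length(vals) >= 1L
    prob[k] <- if (keep[k]) {
      if (stat == "max") max(vals) else mean(vals)
    } else NA_real_
  }
  if (any(!keep))
    message(sprintf("excluded %d segment(s) with no defined probability",
                    sum(!keep)))
  out <- tm[keep, ]
  out$prob <- prob[keep]
  out$group <- ifelse(out$prob >= cutoff, "high", "low")
  out
}

#' Distribution of degron-region probabilities over bins
#'
#' Histograms the maximum probability of each degron region per group
#' (e.g. all degrons, TMD degrons, non-TMD degrons) over equal-width bins
#' spanning the callable range, normalized within group.
#'
#' @param groups Named list of numeric vectors of region maximum
#'   probabilities.
#' @param n_bins Number of equal-width bins (default 3).
#' @param range Probability range covered (default `c(0.85, 1)`).
#' @return Tibble (`group`, `bin` label, `lower`, `upper`, `frequency`);
#'   frequencies sum to 1 within each non-empty group.
#' @export
probability_bin_distribution <- function(groups, n_bins = 3L,
                                         range = c(0.85, 1)) {
  edges <- seq(range[1], range[2], length.out = n_bins + 1L)
  out <- lapply(names(groups), function(g) {
    v <- groups[[g]]
    if (!length(v)) {
      message("empty group: ", g)
      return(NULL)
    }
    counts <- table(cut(v, edges, include.lowest = TRUE))
    tibble::tibble(group = g,
                   bin = names(counts),
                   lower = edges[-length(edges)],
                   upper = edges[-1],
                   frequency = as.numeric(counts) / length(v))
  })
  do.call(rbind, out)
}

#' Amino-acid composition contrast between two sequence groups
#'
#' Compares the mean per-amino-acid composition of two groups of segments
#' (e.g. high- vs low-degron-probability TMDs): an omnibus chi-square test
#' on the pooled 2 x 20 residue-count table (df = 19) followed by a
#' per-amino-acid two-sided Mann-Whitney U test on the per-segment
#' fractions. Normal-approximation 95% confidence intervals on the group
#' means are reported for plotting.
#'
#' @param high,low Character vectors of segment sequences.
#' @return List with `table` (per amino acid: group means, CIs, U-test p),
#'   `chisq` (htest), and group sizes.
#' @export
composition_contrast <- function(high, low) {
  if (!length(high) || !length(low))
    stop("both groups must be non-empty", call. = FALSE)
  if (length(high) < 2L || length(low) < 2L)
    stop("need at least 2 sequences per group for the U test", call. = FALSE)
  comp_h <- aa_composition(high)
  comp_l <- aa_composition(low)
  counts_h <- colSums(comp_h * nchar(high))
  counts_l <- colSums(comp_l * nchar(low))
  chisq <- suppressWarnings(stats::chisq.test(rbind(counts_h, counts_l)))
  ci <- function(x) 1.96 * stats::sd(x) / sqrt(length(x))
  tab <- tibble::tibble(
    aa = AA_ALPHABET20,
    mean_high = colMeans(comp_h),
    mean_low = colMeans(comp_l),
    ci_high = apply(comp_h, 2, ci),
    ci_low = apply(comp_l, 2, ci),
    p_mwu = vapply(AA_ALPHABET20, function(a)
      suppressWarnings(stats::wilcox.test(comp_h[, a], comp_l[, a],
                                          exact = FALSE)$p.value),
      numeric(1)))
  list(table = tab, chisq = chisq,
       n_high = length(high), n_low = length(low))
}
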