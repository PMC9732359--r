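# PSI scoring of FACS-gate read counts, screen filters/labels, and the
# multi-strain E3-knockout delta-PSI stabilization analysis.

GATE_COLS <- c("G1", "G2", "G3", "G4")

.check_counts <- function(counts) {
  need <- c("peptide_id", GATE_COLS)
  miss <- setdiff(need, names(counts))
  if (length(miss))
    stop("count table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  m <- as.matrix(counts[, GATE_COLS])
  if (any(is.na(m)) || any(m < 0))
    stop("gate counts must be non-negative and non-missing", call. = FALSE)
  dup <- unique(counts$peptide_id[duplicated(counts$peptide_id)])
  if (length(dup))
    stop("duplicate peptide_id in count table: ",
         paste(utils::head(dup, 5), collapse = ", "), call. = FALSE)
  invisible(m)
}

#' Read a per-gate read-count table for one strain
#'
#' Expects a TSV with columns `peptide_id`, optionally `sequence`, and the
#' four sort-gate counts `G1`..`G4`. Sequences mapping ambiguously to more
#' than one library member are dropped (the only interpretation available
#' for ambiguity filtering at the count level).
#'
#' @param path TSV path.
#' @param strain Strain label; defaults to the file stem.
#' @return Tibble of counts with attribute `"strain"`.
#' @export
read_gate_counts <- function(path, strain = NULL) {
  if (is.null(strain))
    strain <- sub("\\.[^.]*$", "", basename(path))
  counts <- tibble::as_tibble(utils::read.delim(path, stringsAsFactors = FALSE,
                                                check.names = FALSE))
  .check_counts(counts)
  if ("sequence" %in% names(counts)) {
    amb <- counts$sequence[duplicated(counts$sequence)]
    if (length(amb)) {
      drop <- counts$sequence %in% amb
      message(sprintf("dropped %d row(s) with ambiguous sequences", sum(drop)))
      counts <- counts[!drop, ]
    }
  }
  attr(counts, "strain") <- strain
  counts
}

#' Convert gate counts to within-gate frequencies
#'
#' Each gate holds an equal number of sorted cells but is sequenced to a
#' different depth, so counts are converted to frequencies
#' `f_ig = count_ig / total reads in gate g` before the stability index is
#' computed. A gate with zero total reads yields zero frequencies.
#'
#' @param counts Count tibble with `peptide_id` and `G1`..`G4`.
#' @return The table with added frequency columns `f1`..`f4`; per-gate totals
#'   are attached as attribute `"gate_totals"`.
#' @export
normalize_gates <- function(counts) {
  m <- .check_counts(counts)
  totals <- colSums(m)
  if (all(totals == 0))
    stop("all four gate totals are zero", call. = FALSE)
  f <- sweep(m, 2, ifelse(totals > 0, totals, 1), "/")
  f[, totals == 0] <- 0
  out <- counts
  out[paste0("f", 1:4)] <- as.data.frame(f)
  attr(out, "gate_totals") <- totals
  attr(out, "strain") <- attr(counts, "strain")
  out
}

#' Compute Protein Stability Index (PSI) scores
#'
#' The PSI of peptide i is the gate-index-weighted mean of its gate
#' frequencies, `PSI_i = sum_g g * f_ig / sum_g f_ig` with gates numbered
#' 1 (least stable) to 4 (most stable), so PSI lies in \[1, 4\]: 1 means
#' maximally unstable, 4 maximally stable. Peptides with no reads in any
#' gate cannot be scored and are dropped with a message.
#'
#' Rows are labelled for model training (`unstable` below `unstable_max`,
#' `stable` above `stable_min`, otherwise `intermediate`) and flagged as
#' degrons below `degron_cutoff` (comparator configurable, default strict
#' `<`).
#'
#' @param counts Count tibble (`peptide_id`, `G1`..`G4`); frequencies are
#'   computed via [normalize_gates()] unless `f1`..`f4` are already present.
#' @param unstable_max PSI below which a tile is labelled unstable (2.2).
#' @param stable_min PSI above which a tile is labelled stable (2.8).
#' @param degron_cutoff PSI cutoff for the degron flag (1.7).
#' @param degron_comparator `"lt"` (strict, default) or `"le"`.
#' @return A `psi_table` tibble: `peptide_id`, `psi`, `total_reads`, `label`,
#'   `is_degron` (plus `sequence` when present in the input).
#' @export
compute_psi <- function(counts, unstable_max = 2.2, stable_min = 2.8,
                        degron_cutoff = 1.7,
                        degron_comparator = c("lt", "le")) {
  degron_comparator <- match.arg(degron_comparator)
  if (unstable_max >= stable_min)
    stop("unstable_max must be below stable_min", call. = FALSE)
  if (!all(paste0("f", 1:4) %in% names(counts)))
    counts <- normalize_gates(counts)
  f <- as.matrix(counts[, paste0("f", 1:4)])
  fs <- rowSums(f)
  dropped <- fs == 0
  if (any(dropped))
    message(sprintf("dropped %d peptide(s) with zero frequency in all gates",
                    sum(dropped)))
  keep <- counts[!dropped, ]
  f <- f[!dropped, , drop = FALSE]
  psi <- as.vector(f %*% (1:4)) / rowSums(f)
  total <- as.integer(rowSums(as.matrix(keep[, GATE_COLS])))
  out <- tibble::tibble(
    peptide_id = keep$peptide_id,
    psi = psi,
    total_reads = total,
    label = ifelse(psi < unstable_max, "unstable",
                   ifelse(psi > stable_min, "stable", "intermediate")),
    is_degron = if (degron_comparator == "lt") psi < degron_cutoff
                else psi <= degron_cutoff
  )
  if ("sequence" %in% names(keep)) out$sequence <- keep$sequence
  attr(out, "strain") <- attr(counts, "strain")
  attr(out, "degron_cutoff") <- degron_cutoff
  attr(out, "degron_comparator") <- degron_comparator
  class(out) <- c("psi_table", class(out))
  out
}

#' Drop low-coverage library members
#'
#' Keeps peptides whose total raw reads across the four gates are strictly
#' greater than `min_reads` (default 50, the screen's training-set filter).
#'
#' @param counts Count tibble.
#' @param min_reads Strict lower bound on total reads.
#' @return Filtered count tibble.
#' @export
filter_low_coverage <- function(counts, min_reads = 50L) {
  m <- .check_counts(counts)
  keep <- rowSums(m) > min_reads
  out <- counts[keep, ]
  attr(out, "strain") <- attr(counts, "strain")
  out
}

#' Extract the labelled training subset from a PSI table
#'
#' Tiles with PSI below `unstable_max` are degron (unstable) training
#' examples, tiles above `stable_min` non-degron (stable) examples; the
#' intermediate band is excluded from training.
#'
#' @param psi A `psi_table` from [compute_psi()].
#' @param unstable_max,stable_min Label thresholds (defaults 2.2 / 2.8).
#' @return The subset with `label` in `unstable`/`stable`.
#' @export
label_for_training <- function(psi, unstable_max = 2.2, stable_min = 2.8) {
  if (unstable_max >= stable_min)
    stop("unstable_max must be below stable_min", call. = FALSE)
  lab <- ifelse(psi$psi < unstable_max, "unstable",
                ifelse(psi$psi > stable_min, "stable", "intermediate"))
  out <- psi[lab != "intermediate", ]
  out$label <- lab[lab != "intermediate"]
  out
}

#' Call degrons from a PSI table
#'
#' @param psi A `psi_table`.
#' @param cutoff PSI degron cutoff; 1.7 for the standard call, 1.62 for
#'   high-confidence degrons.
#' @param comparator `"lt"` (strict `<`, default) or `"le"`.
#' @return List with `ids` (degron peptide ids), `fraction` (of scored
#'   tiles), `n_degrons`, `n_scored`, and the cutoff/comparator used.
#' @export
call_degrons <- function(psi, cutoff = 1.7, comparator = c("lt", "le")) {
  comparator <- match.arg(comparator)
  hit <- if (comparator == "lt") psi$psi < cutoff else psi$psi <= cutoff
  list(ids = psi$peptide_id[hit],
       fraction = mean(hit),
       n_degrons = sum(hit),
       n_scored = nrow(psi),
       cutoff = cutoff,
       comparator = comparator)
}

#' E3-knockout delta-PSI stabilization analysis
#'
#' For each knockout strain, restricts to peptides called degrons in the
#' control strain (PSI at or below `degron_cutoff`) and shared with the
#' knockout, computes `delta_psi = psi_knockout - psi_control`, and calls a
#' peptide stabilized when its delta-PSI exceeds the per-strain threshold
#' `mean(delta_psi) + 2 * SE(delta_psi)`. By default SE is the standard
#' error of the strain's delta-PSI distribution (`sd/sqrt(n)`);
#' `se_method = "sd"` uses two standard deviations instead.
#'
#' @param control `psi_table` for the control strain.
#' @param knockouts Named list of `psi_table`s, one per knockout strain.
#' @param degron_cutoff Control-degron PSI cutoff (default 1.7, inclusive).
#' @param se_method `"se"` (sd/sqrt(n), default) or `"sd"`.
#' @return Named list of `delta_psi_result`s, each with `strain`, `table`
#'   (peptide_id, psi_control, psi_ko, delta_psi), `threshold`,
#'   `stabilized` ids, and `percent_stabilized`.
#' @export
delta_psi_analysis <- function(control, knockouts, degron_cutoff = 1.7,
                               se_method = c("se", "sd")) {
  se_method <- match.arg(se_method)
  if (!is.list(knockouts) || is.null(names(knockouts)) ||
      any(!nzchar(names(knockouts))))
    stop("knockouts must be a named list of psi_tables", call. = FALSE)
  degrons <- control[control$psi <= degron_cutoff, c("peptide_id", "psi")]
  lapply(stats::setNames(names(knockouts), names(knockouts)), function(st) {
    ko <- knockouts[[st]]
    shared <- merge(degrons, ko[, c("peptide_id", "psi")],
                    by = "peptide_id", suffixes = c("_control", "_ko"))
    if (nrow(shared) < 3L)
      stop(sprintf("strain '%s': fewer than 3 control degrons shared", st),
           call. = FALSE)
    shared$delta_psi <- shared$psi_ko - shared$psi_control
    se <- if (se_method == "se")
      stats::sd(shared$delta_psi) / sqrt(nrow(shared))
    else stats::sd(shared$delta_psi)
    threshold <- mean(shared$delta_psi) + 2 * se
    stab <- shared$peptide_id[shared$delta_psi > threshold]
    structure(list(strain = st,
                   table = tibble::as_tibble(shared),
                   threshold = threshold,
                   se_method = se_method,
                   stabilized = stab,
                   percent_stabilized = 100 * length(stab) / nrow(shared)),
              class = "delta_psi_result")
  })
}

#' Functional overlap of E3 ligases over top delta-PSI degrons
#'
#' Takes, per strain, the `ceiling(top_fraction * n)` peptides with the
#' largest delta-PSI (ties at the cutoff broken by peptide id for
#' determinism) and reports all Venn intersection-region cardinalities plus
#' the fraction of peptides shared by two or more strains.
#'
#' @param results Named list of `delta_psi_result`s (at least 2 strains).
#' @param top_fraction Fraction of each strain's degrons taken (default 0.10).
#' @return List with `top_sets` (ids per strain), `top_n`, `region_counts`
#'   (named by strain combination, exclusive regions), and
#'   `fraction_multi` (peptides in >= 2 sets among peptides in any set).
#' @export
e3_overlap <- function(results, top_fraction = 0.10) {
  if (length(results) < 2L)
    stop("need at least two strains", call. = FALSE)
  strains <- names(results)
  top_sets <- lapply(results, function(r) {
    tb <- r$table
    n_top <- ceiling(top_fraction * nrow(tb))
    ord <- order(-tb$delta_psi, tb$peptide_id)
    tb$peptide_id[ord[seq_len(n_top)]]
  })
  all_ids <- unique(unlist(top_sets))
  member <- vapply(top_sets, function(s) all_ids %in% s,
                   logical(length(all_ids)))
  if (length(all_ids) == 1L) member <- matrix(member, nrow = 1L,
                                              dimnames = list(NULL, strains))
  key <- apply(member, 1, function(row) paste(strains[row], collapse = "&"))
  region_counts <- table(key)
  list(top_sets = top_sets,
       top_n = vapply(top_sets, length, integer(1)),
       region_counts = stats::setNames(as.integer(region_counts),
                                       names(region_counts)),
       fraction_multi = mean(rowSums(member) >= 2))
}

#' Write a PSI table to TSV
#'
#' @param psi A `psi_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_psi <- function(psi, path) {
  utils::write.table(as.data.frame(psi), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a PSI table written by [write_psi()] (or any TSV with at least
#' `peptide_id` and `psi` columns)
#'
#' @param path TSV path.
#' @param strain Optional strain label.
#' @return A `psi_table` tibble.
#' @export
read_psi <- function(path, strain = NULL) {
  out <- tibble::as_tibble(utils::read.delim(path, stringsAsFactors = FALSE))
  if (!all(c("peptide_id", "psi") %in% names(out)))
    stop("PSI table needs 'peptide_id' and 'psi' columns", call. = FALSE)
  attr(out, "strain") <- strain
  class(out) <- c("psi_table", class(out))
  out
}
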