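# Sequence utilities shared by every stage: FASTA I/O, peptide tiling,
# Kyte-Doolittle hydropathy and amino-acid composition.

#' The twenty standard amino acids, alphabetical one-letter order
#'
#' @format Character vector of length 20.
#' @export
AA_ALPHABET20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                   "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Kyte-Doolittle hydropathy scale
#'
#' Per-residue hydropathy values from Kyte & Doolittle (1982), J Mol Biol
#' 157:105-132, embedded verbatim so the scale cannot drift silently.
#'
#' @format Named numeric vector, one value per standard amino acid.
#' @export
KYTE_DOOLITTLE <- c(
  A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
  L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2
)[AA_ALPHABET20]

# residues outside the modelled alphabet that sanitization has to handle
.nonstandard <- c("X", "U", "B", "Z", "O", "J", "*")

.check_sequence <- function(sequence, what = "sequence") {
  if (length(sequence) != 1L || is.na(sequence) || !nzchar(sequence))
    stop(what, " must be a single non-empty string", call. = FALSE)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% AA_ALPHABET20)
  if (length(bad))
    stop(sprintf("invalid residue '%s' at position %d in %s",
                 chars[bad[1]], bad[1], what), call. = FALSE)
  chars
}

#' Read protein sequences from a FASTA file
#'
#' Sequences are upper-cased and sanitized: residues outside the 20-letter
#' alphabet (X, U, B, Z, ...) cannot be scored by a model with exactly one
#' parameter per standard amino acid, so affected proteins are either
#' excluded entirely (`policy = "drop"`, the default, appropriate for model
#' training and proteome scanning) or kept and handled at tiling time
#' (`policy = "skip-tile"`, see [tile_proteins()]).
#'
#' @param path Path to a (multi-)FASTA file of protein sequences.
#' @param policy Sanitization policy for nonstandard residues.
#' @return A tibble with columns `id` and `sequence`, one row per retained
#'   record, input order preserved. Dropped ids are attached as attribute
#'   `"dropped"`; under `"skip-tile"` the retained nonstandard sequences are
#'   flagged in the logical column `has_nonstandard`.
#' @export
read_fasta <- function(path, policy = c("drop", "skip-tile")) {
  policy <- match.arg(policy)
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L) stop("FASTA file is empty: ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(aa))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate FASTA ids: ", paste(dup, collapse = ", "), call. = FALSE)
  seqs <- toupper(as.character(aa))
  nonstd <- grepl(paste0("[^", paste(AA_ALPHABET20, collapse = ""), "]"), seqs)
  out <- tibble::tibble(id = ids, sequence = unname(seqs),
                        has_nonstandard = unname(nonstd))
  dropped <- character(0)
  if (policy == "drop" && any(nonstd)) {
    dropped <- out$id[nonstd]
    warning(sprintf("dropped %d record(s) with nonstandard residues: %s",
                    length(dropped), paste(dropped, collapse = ", ")),
            call. = FALSE)
    out <- out[!nonstd, ]
  }
  attr(out, "dropped") <- dropped
  attr(out, "policy") <- policy
  out
}

#' Tile a protein sequence into overlapping peptide windows
#'
#' Library mode uses 17-residue windows stepped by 5 (12-residue overlaps,
#' mirroring DNA tiling at 15-bp steps); proteome scanning uses
#' `window = 17, step = 1`. With `anchor_tail = TRUE` a final window anchored
#' at the C-terminus (start `L - window + 1`) is appended whenever the last
#' regular window does not already reach it.
#'
#' @param sequence Amino-acid string of length >= `window`.
#' @param window Window length in residues (default 17).
#' @param step Start-to-start increment (default 5).
#' @param anchor_tail Append a C-terminal-anchored final tile if needed.
#' @param protein_id Optional id carried into the output.
#' @return Tibble with columns `protein_id`, `start`, `end`, `sequence`;
#'   coordinates are 1-based inclusive.
#' @export
tile_sequence <- function(sequence, window = 17L, step = 5L,
                          anchor_tail = FALSE, protein_id = NA_character_) {
  chars <- .check_sequence(sequence)
  L <- length(chars)
  if (window < 1L || step < 1L)
    stop("window and step must be positive", call. = FALSE)
  if (L < window)
    stop(sprintf("sequence%s of length %d is shorter than window %d",
                 if (is.na(protein_id)) "" else paste0(" '", protein_id, "'"),
                 L, window), call. = FALSE)
  starts <- .tile_starts(L, window, step, anchor_tail)
  tibble::tibble(
    protein_id = protein_id,
    start = as.integer(starts),
    end = as.integer(starts + window - 1L),
    sequence = substring(sequence, starts, starts + window - 1L)
  )
}

.tile_starts <- function(L, window, step, anchor_tail) {
  starts <- seq.int(1L, L - window + 1L, by = step)
  if (anchor_tail && starts[length(starts)] != L - window + 1L)
    starts <- c(starts, L - window + 1L)
  as.integer(starts)
}

#' Tile every protein in a record table
#'
#' Applies [tile_sequence()] to each row of a [read_fasta()] table. Under the
#' `"skip-tile"` sanitization policy, tiles containing nonstandard residues
#' are excluded (with a message) rather than the whole protein.
#'
#' @inheritParams tile_sequence
#' @param proteins Tibble with `id` and `sequence` columns.
#' @return Tibble of tiles with an added `peptide_id` column
#'   (`<protein_id>_<start>`).
#' @export
tile_proteins <- function(proteins, window = 17L, step = 5L,
                          anchor_tail = FALSE) {
  valid_re <- paste0("^[", paste(AA_ALPHABET20, collapse = ""), "]+$")
  out <- lapply(seq_len(nrow(proteins)), function(i) {
    s <- proteins$sequence[i]
    if (!grepl(valid_re, s)) {
      # skip-tile policy: drop only the windows covering nonstandard residues
      if (nchar(s) < window)
        stop(sprintf("sequence '%s' of length %d is shorter than window %d",
                     proteins$id[i], nchar(s), window), call. = FALSE)
      starts <- .tile_starts(nchar(s), window, step, anchor_tail)
      tl <- tibble::tibble(
        protein_id = proteins$id[i],
        start = starts, end = starts + as.integer(window) - 1L,
        sequence = substring(s, starts, starts + window - 1L)
      )
      bad <- !grepl(valid_re, tl$sequence)
      if (any(bad))
        message(sprintf("%s: skipped %d tile(s) with nonstandard residues",
                        proteins$id[i], sum(bad)))
      tl[!bad, ]
    } else {
      tile_sequence(s, window, step, anchor_tail,
                    protein_id = proteins$id[i])
    }
  })
  out <- do.call(rbind, out)
  out$peptide_id <- paste0(out$protein_id, "_", out$start)
  out[, c("peptide_id", "protein_id", "start", "end", "sequence")]
}

#' Grand average of hydropathy (GRAVY)
#'
#' Mean Kyte-Doolittle hydropathy over a sequence. Bounded by the scale's
#' extremes \[-4.5, 4.5\] and invariant to residue order.
#'
#' @param sequence Amino-acid string, or character vector of them.
#' @return Numeric GRAVY value(s) in Kyte-Doolittle units.
#' @export
gravy <- function(sequence) {
  vapply(sequence, function(s) {
    chars <- .check_sequence(s)
    mean(KYTE_DOOLITTLE[chars])
  }, numeric(1), USE.NAMES = length(sequence) > 1L)
}

#' Amino-acid composition fractions
#'
#' Fraction of each of the 20 standard amino acids in a sequence. The
#' composition is an order-free statistic: it is identical for any
#' permutation of the sequence and always sums to 1.
#'
#' @param sequence Amino-acid string, or character vector of them.
#' @return For one sequence a named numeric vector of length 20; for several
#'   a matrix with one row per sequence, columns in [AA_ALPHABET20] order.
#' @export
aa_composition <- function(sequence) {
  one <- function(s) {
    chars <- .check_sequence(s)
    tab <- table(factor(chars, levels = AA_ALPHABET20))
    as.numeric(tab) / length(chars)
  }
  if (length(sequence) == 1L) {
    out <- one(sequence)
    names(out) <- AA_ALPHABET20
    out
  } else {
    out <- t(vapply(sequence, one, numeric(20L)))
    colnames(out) <- AA_ALPHABET20
    rownames(out) <- names(sequence)
    out
  }
}

#' Randomly scramble a peptide sequence
#'
#' Draws a uniformly random permutation of the residues; length and
#' composition are preserved, so any composition-only score is unchanged.
#' Reproducible for a fixed seed.
#'
#' @param sequence Amino-acid string.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return The scrambled sequence.
#' @export
scramble <- function(sequence, seed = NULL) {
  chars <- .check_sequence(sequence)
  if (!is.null(seed)) {
    old <- .save_rng()
    on.exit(.restore_rng(old))
    set.seed(seed)
  }
  paste(sample(chars), collapse = "")
}

# preserve/restore the caller's RNG state around seeded operations
.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Write tiles to a TSV file
#'
#' @param tiles Tile tibble from [tile_sequence()] or [tile_proteins()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tiles <- function(tiles, path) {
  utils::write.table(tiles, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
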