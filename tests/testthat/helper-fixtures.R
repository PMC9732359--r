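# Shared fixture builders: everything is generated in code at test time.

make_counts <- function(ids, counts, sequences = NULL) {
  m <- matrix(counts, ncol = 4, byrow = TRUE)
  out <- tibble::tibble(peptide_id = ids,
                        G1 = m[, 1], G2 = m[, 2], G3 = m[, 3], G4 = m[, 4])
  if (!is.null(sequences)) out$sequence <- sequences
  out
}

make_psi_table <- function(ids, psi) {
  out <- tibble::tibble(peptide_id = ids, psi = psi,
                        total_reads = NA_integer_,
                        label = NA_character_, is_degron = NA)
  class(out) <- c("psi_table", class(out))
  out
}

# a degron_profile built directly, for interval-arithmetic tests
make_profile <- function(protein_id, length, prob_at = numeric(0),
                         cutoff = 0.85) {
  track <- rep(NA_real_, length)
  if (length >= 17) track[9:(length - 8)] <- 0.1
  track[as.integer(names(prob_at))] <- unname(prob_at)
  hit <- which(!is.na(track) & track >= cutoff)
  regions <- tibble::tibble(start = integer(), end = integer(),
                            tile_start = integer(), tile_end = integer(),
                            center = integer(), max_prob = numeric())
  if (length(hit)) {
    brk <- c(0, which(diff(hit) > 1), length(hit))
    regions <- do.call(rbind, lapply(seq_len(length(brk) - 1), function(k) {
      run <- hit[(brk[k] + 1):brk[k + 1]]
      tibble::tibble(start = min(run), end = max(run),
                     tile_start = min(run) - 8L, tile_end = max(run) + 8L,
                     center = as.integer(floor((min(run) + max(run)) / 2)),
                     max_prob = max(track[run]))
    }))
  }
  structure(list(protein_id = protein_id, length = length,
                 probability = track, regions = regions,
                 cutoff = cutoff, comparator = "ge"),
            class = "degron_profile")
}

random_peptide <- function(n = 1, len = 17, prob = NULL) {
  vapply(seq_len(n), function(i)
    paste(sample(degronscan::AA_ALPHABET20, len, replace = TRUE,
                 prob = prob), collapse = ""), character(1))
}

write_temp_fasta <- function(records) {
  path <- tempfile(fileext = ".fa")
  writeLines(unlist(lapply(names(records), function(id)
    c(paste0(">", id), records[[id]]))), path)
  path
}
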