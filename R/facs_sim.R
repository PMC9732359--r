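# Generative model of a pooled GPS stability screen: tile library ->
# per-cell fluorescence ratios -> equal-occupancy 4-gate sort ->
# multinomial read sampling per gate.

# Approximate S. cerevisiae proteome amino-acid frequencies (UniProt
# reference proteome, rounded); used as the default background residue
# distribution for simulated tile libraries.
YEAST_AA_FREQ <- c(
  A = 0.055, C = 0.013, D = 0.058, E = 0.064, F = 0.045,
  G = 0.050, H = 0.022, I = 0.066, K = 0.073, L = 0.096,
  M = 0.021, N = 0.061, P = 0.044, Q = 0.039, R = 0.044,
  S = 0.090, T = 0.059, V = 0.056, W = 0.010, Y = 0.034
)

#' Configuration for a simulated stability screen
#'
#' Defaults describe the screen the simulator emulates: a large tiled
#' library (17-mers), lognormal cell-to-cell fluorescence noise, an
#' equal-occupancy four-gate sort, and multinomial sequencing of each gate
#' at a depth averaging ~100 reads per tile.
#'
#' @param n_tiles Number of library members.
#' @param weights True per-amino-acid degron weights: `"KD"` (the
#'   Kyte-Doolittle hydropathy scale, hydrophobicity-driven degrons) or a
#'   named 20-vector.
#' @param cells_per_tile Sorted cells per library member.
#' @param sigma Lognormal sdlog of per-cell fluorescence-ratio noise.
#' @param reads_per_gate Sequencing reads drawn per gate
#'   (default `25 * n_tiles`, i.e. ~100 reads per tile over four gates).
#' @param ratio_range Mean fluorescence ratio at degron probability 0 and 1;
#'   the probability-to-ratio map is linear between them (only its
#'   monotonicity matters for rank-based recovery).
#' @param gate_quantiles Pooled-population quantiles at the three gate
#'   boundaries (default quartiles, giving equal cell numbers per gate).
#' @param background Residue sampling distribution (default yeast-like).
#' @param seed Random seed recorded and used by [simulate_library()] /
#'   [simulate_sort()].
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_tiles = 20000L, weights = "KD",
                       cells_per_tile = 100L, sigma = 0.3,
                       reads_per_gate = 25L * n_tiles,
                       ratio_range = c(1.0, 0.2),
                       gate_quantiles = c(0.25, 0.5, 0.75),
                       background = YEAST_AA_FREQ, seed = 1L) {
  if (identical(weights, "KD")) weights <- KYTE_DOOLITTLE
  if (is.null(names(weights)) && length(weights) == 20L)
    names(weights) <- AA_ALPHABET20
  stopifnot(n_tiles > 0, cells_per_tile > 0, sigma >= 0,
            reads_per_gate > 0, length(gate_quantiles) == 3,
            all(diff(gate_quantiles) > 0))
  background <- background / sum(background)
  structure(list(n_tiles = as.integer(n_tiles), weights = weights,
                 cells_per_tile = as.integer(cells_per_tile), sigma = sigma,
                 reads_per_gate = as.integer(reads_per_gate),
                 ratio_range = ratio_range, gate_quantiles = gate_quantiles,
                 background = background, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a tiled peptide library with ground-truth stabilities
#'
#' Draws random 17-mers from the background residue distribution, computes
#' each tile's true degron probability through the composition-weight link
#' (sigmoid of the weight-composition inner product) and maps probability to
#' a true mean fluorescence ratio with the configured monotone-decreasing
#' linear map.
#'
#' @param config A [sim_config()].
#' @return Tibble (`peptide_id`, `sequence`, `true_prob`, `true_ratio`)
#'   with the config attached as attribute `"config"`.
#' @export
simulate_library <- function(config) {
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(config$seed)
  res <- sample(AA_ALPHABET20, 17L * config$n_tiles, replace = TRUE,
                prob = config$background)
  seqs <- apply(matrix(res, nrow = 17L), 2, paste, collapse = "")
  comp <- aa_composition(seqs)
  prob <- sigmoid(as.vector(comp %*% config$weights[AA_ALPHABET20]))
  r0 <- config$ratio_range[1]; r1 <- config$ratio_range[2]
  tibble::tibble(peptide_id = sprintf("tile%06d", seq_len(config$n_tiles)),
                 sequence = seqs,
                 true_prob = prob,
                 true_ratio = r0 + (r1 - r0) * prob) -> out
  attr(out, "config") <- config
  out
}

#' Simulate the FACS sort and per-gate sequencing
#'
#' Each cell's fluorescence ratio is its tile's true mean ratio times a
#' lognormal noise factor. The pooled population is ranked and split at the
#' configured quantiles (default quartiles) so the four gates hold equal
#' cell numbers; ties (e.g. at `sigma = 0`) are broken by pool order, which
#' keeps a tile's cells contiguous. Reads are then drawn per gate from a
#' multinomial over tiles proportional to the tile's cell occupancy of that
#' gate.
#'
#' @param truth Library tibble from [simulate_library()].
#' @param config A [sim_config()]; defaults to the one attached to `truth`.
#' @param ratio_scale Optional per-tile multiplier on the true mean ratio
#'   (named by peptide_id or a full-length vector), used to inject e.g.
#'   knockout stabilization offsets.
#' @param seed Seed for the sort and sequencing draws; defaults to
#'   `config$seed + 1`.
#' @return Count tibble (`peptide_id`, `sequence`, `G1`..`G4`) with the
#'   per-tile gate occupancy matrix attached as attribute `"occupancy"`.
#' @export
simulate_sort <- function(truth, config = attr(truth, "config"),
                          ratio_scale = NULL, seed = config$seed + 1L) {
  stopifnot(inherits(config, "sim_config"))
  n <- nrow(truth)
  if (config$reads_per_gate < n)
    warning("reads per gate below library size; counts will be sparse",
            call. = FALSE)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  ratio <- truth$true_ratio
  if (!is.null(ratio_scale)) {
    if (!is.null(names(ratio_scale))) {
      scale <- rep(1, n)
      idx <- match(names(ratio_scale), truth$peptide_id)
      if (anyNA(idx)) stop("ratio_scale names not in library", call. = FALSE)
      scale[idx] <- ratio_scale
      ratio_scale <- scale
    }
    ratio <- ratio * ratio_scale
  }
  cells <- config$cells_per_tile
  tile_of_cell <- rep.int(seq_len(n), rep.int(cells, n))
  cell_ratio <- rep.int(ratio, rep.int(cells, n))
  if (config$sigma > 0)
    cell_ratio <- cell_ratio * stats::rlnorm(length(cell_ratio), 0,
                                             config$sigma)
  # equal-occupancy gating: rank cells, cut at the configured quantiles
  total <- length(cell_ratio)
  rnk <- rank(cell_ratio, ties.method = "first")
  cuts <- floor(config$gate_quantiles * total)
  gate <- findInterval(rnk, c(cuts + 0.5)) + 1L   # 1..4, gate 1 = lowest
  occupancy <- matrix(tabulate(tile_of_cell + n * (gate - 1L), nbins = 4L * n),
                      nrow = n, dimnames = list(truth$peptide_id, GATE_COLS))
  counts <- vapply(1:4, function(g) {
    occ <- occupancy[, g]
    if (sum(occ) == 0) return(integer(n))
    as.integer(stats::rmultinom(1, config$reads_per_gate, occ / sum(occ)))
  }, integer(n))
  out <- tibble::tibble(peptide_id = truth$peptide_id,
                        sequence = truth$sequence)
  out[GATE_COLS] <- as.data.frame(counts)
  attr(out, "occupancy") <- occupancy
  attr(out, "config") <- config
  attr(out, "strain") <- "simulated"
  out
}

#' Run a full simulated screen
#'
#' Convenience wrapper: [simulate_library()] then [simulate_sort()].
#'
#' @param config A [sim_config()].
#' @return List with `truth` (library tibble) and `counts` (gate counts).
#' @export
simulate_screen <- function(config = sim_config()) {
  truth <- simulate_library(config)
  list(truth = truth, counts = simulate_sort(truth, config))
}

#' Summarize how well the pipeline recovered the simulated ground truth
#'
#' @param truth Library tibble from [simulate_library()].
#' @param model Fitted `degron_model` (or `NULL` to skip weight metrics).
#' @param psi `psi_table` computed from the simulated counts (or `NULL`).
#' @param cutoff Degron-probability cutoff for the call metrics.
#' @return List of metrics: `weight_pearson` (fitted vs true weights),
#'   `psi_spearman` (PSI vs true mean ratio), and degron-call
#'   `sensitivity`/`specificity` at `cutoff` (NA with a note when a class
#'   is absent in truth).
#' @export
recovery_report <- function(truth, model = NULL, psi = NULL,
                            cutoff = 0.85) {
  config <- attr(truth, "config")
  out <- list(n_tiles = nrow(truth), seed = config$seed)
  if (!is.null(model)) {
    tw <- config$weights[AA_ALPHABET20]
    out$weight_pearson <- if (stats::sd(tw) == 0 ||
                              stats::sd(model$weights) == 0) NA_real_
      else stats::cor(unname(model$weights[AA_ALPHABET20]), unname(tw))
    true_deg <- truth$true_prob >= cutoff
    pred <- predict(model, truth$sequence) >= cutoff
    out$sensitivity <- if (any(true_deg)) mean(pred[true_deg]) else {
      out$note <- "no true degrons at this cutoff; sensitivity undefined"
      NA_real_
    }
    out$specificity <- if (any(!true_deg)) mean(!pred[!true_deg])
                       else NA_real_
  }
  if (!is.null(psi)) {
    m <- match(psi$peptide_id, truth$peptide_id)
    out$psi_spearman <- stats::cor(psi$psi, truth$true_ratio[m],
                                   method = "spearman")
  }
  out
}
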