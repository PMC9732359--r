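# Composition-based logistic degron predictor: one weight per amino acid,
# trained on stable/unstable tile labels, applied by sliding a 17-residue
# window along proteins.

sigmoid <- function(x) 1 / (1 + exp(-x))

# Ridge-penalized logistic regression by Newton iteration on the penalized
# log-likelihood; deterministic, no stochastic elements. Objective:
#   -(1/n) loglik + (lambda/2) ||w||^2   (intercept never penalized)
.fit_ridge_logistic <- function(X, y, lambda, intercept = FALSE,
                                tol = 1e-8, max_iter = 100L) {
  if (intercept) X <- cbind(`(Intercept)` = 1, X)
  p <- ncol(X)
  n <- nrow(X)
  pen <- rep(lambda, p)
  if (intercept) pen[1] <- 0
  w <- numeric(p)
  for (iter in seq_len(max_iter)) {
    eta <- as.vector(X %*% w)
    mu <- sigmoid(eta)
    grad <- as.vector(crossprod(X, mu - y)) / n + pen * w
    if (max(abs(grad)) < tol)
      return(list(coef = stats::setNames(w, colnames(X)),
                  iterations = iter - 1L, converged = TRUE,
                  grad_norm = max(abs(grad))))
    wt <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(X * wt, X) / n + diag(pen, p)
    w <- w - solve(H, grad)
  }
  eta <- as.vector(X %*% w)
  grad <- as.vector(crossprod(X, sigmoid(eta) - y)) / n + pen * w
  list(coef = stats::setNames(w, colnames(X)), iterations = max_iter,
       converged = max(abs(grad)) < tol, grad_norm = max(abs(grad)))
}

.binomial_deviance <- function(y, p) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -2 * mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Train the composition-based degron model
#'
#' Fits `P(degron | tile) = sigmoid(sum_a w_a * fraction_a)` over the 20
#' amino-acid composition fractions of 17-mer tiles by ridge-penalized
#' maximum likelihood (deterministic Newton iterations, gradient tolerance
#' 1e-8). With fractions summing to 1 an intercept is not identifiable (it
#' can be absorbed as a constant shift of all 20 weights), so none is fitted
#' by default. The ridge strength is chosen by k-fold cross-validation over
#' a log-spaced grid unless `lambda` is given; fold assignment uses a fixed
#' seed, so training is reproducible.
#'
#' Because prediction depends only on composition, the model scores any
#' permutation of a sequence identically.
#'
#' @param sequences Character vector of 17-mer tile sequences (or a
#'   precomputed composition matrix with 20 columns).
#' @param labels Class per tile: logical/0-1 (TRUE/1 = degron) or a character
#'   vector with values `"unstable"` (degron) / `"stable"`.
#' @param lambda Ridge strength; `NULL` (default) selects it by CV over
#'   `lambda_grid`.
#' @param lambda_grid Grid for CV (default `10^(-4:2)`).
#' @param nfolds CV folds (default 5).
#' @param intercept Fit an intercept (off by default; see above).
#' @param fold_seed Seed for CV fold assignment.
#' @return A `degron_model`: list with `weights` (20 named values, log-odds
#'   units per unit composition fraction), `intercept`, `lambda`, `cv`
#'   (deviance per grid point, when CV ran), and training metadata
#'   (`n_unstable`, `n_stable`, convergence info).
#' @export
train_degron_model <- function(sequences, labels, lambda = NULL,
                               lambda_grid = 10^seq(-4, 2), nfolds = 5L,
                               intercept = FALSE, fold_seed = 20L) {
  if (is.matrix(sequences)) {
    X <- sequences
    if (ncol(X) != 20L) stop("composition matrix needs 20 columns",
                             call. = FALSE)
    colnames(X) <- AA_ALPHABET20
  } else {
    if (any(nchar(sequences) != 17L))
      stop("training tiles must all be 17-mers", call. = FALSE)
    X <- aa_composition(sequences)
  }
  y <- if (is.character(labels) || is.factor(labels)) {
    lab <- as.character(labels)
    if (!all(lab %in% c("unstable", "stable")))
      stop("character labels must be 'unstable' or 'stable'", call. = FALSE)
    as.numeric(lab == "unstable")
  } else as.numeric(labels)
  if (length(y) != nrow(X)) stop("labels and tiles differ in length",
                                 call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("training data contain a single class", call. = FALSE)

  cv <- NULL
  if (is.null(lambda)) {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(fold_seed)
    fold <- sample(rep_len(seq_len(nfolds), nrow(X)))
    dev <- vapply(lambda_grid, function(lam) {
      mean(vapply(seq_len(nfolds), function(k) {
        fit <- .fit_ridge_logistic(X[fold != k, , drop = FALSE], y[fold != k],
                                   lam, intercept)
        Xv <- X[fold == k, , drop = FALSE]
        eta <- if (intercept) fit$coef[1] + Xv %*% fit$coef[-1]
               else Xv %*% fit$coef
        .binomial_deviance(y[fold == k], sigmoid(as.vector(eta)))
      }, numeric(1)))
    }, numeric(1))
    # ties toward the stronger penalty
    lambda <- max(lambda_grid[dev <= min(dev) + 1e-12])
    cv <- tibble::tibble(lambda = lambda_grid, deviance = dev)
  }
  fit <- .fit_ridge_logistic(X, y, lambda, intercept)
  if (!fit$converged)
    stop(sprintf("logistic fit did not converge (gradient norm %.3g)",
                 fit$grad_norm), call. = FALSE)
  w <- fit$coef
  b <- 0
  if (intercept) { b <- unname(w[1]); w <- w[-1] }
  structure(list(weights = w,
                 intercept = b,
                 lambda = lambda,
                 cv = cv,
                 n_unstable = sum(y == 1),
                 n_stable = sum(y == 0),
                 iterations = fit$iterations,
                 feature = "composition_fraction",
                 training_digest = sprintf("n=%d;lambda=%g", length(y),
                                           lambda)),
            class = "degron_model")
}

#' @export
print.degron_model <- function(x, ...) {
  cat(sprintf(
    "degron model: 20 amino-acid weights (lambda = %g)\n", x$lambda))
  cat(sprintf("trained on %d unstable / %d stable tiles\n",
              x$n_unstable, x$n_stable))
  print(round(x$weights, 3))
  invisible(x)
}

#' Build a degron model directly from known weights
#'
#' Used by the screen simulator and in analyses where the weights are given
#' rather than trained (e.g. the hydropathy-scale truth model).
#'
#' @param weights Named numeric vector over the 20 amino acids (any order),
#'   or unnamed length-20 in [AA_ALPHABET20] order.
#' @param intercept Optional intercept (default 0).
#' @return A `degron_model`.
#' @export
degron_model <- function(weights, intercept = 0) {
  if (is.null(names(weights))) {
    if (length(weights) != 20L) stop("need 20 weights", call. = FALSE)
    names(weights) <- AA_ALPHABET20
  }
  if (!setequal(names(weights), AA_ALPHABET20))
    stop("weights must cover the 20 standard amino acids", call. = FALSE)
  structure(list(weights = weights[AA_ALPHABET20], intercept = intercept,
                 lambda = NA_real_, cv = NULL, n_unstable = NA_integer_,
                 n_stable = NA_integer_, iterations = 0L,
                 feature = "composition_fraction",
                 training_digest = "fixed-weights"),
            class = "degron_model")
}

.model_eta <- function(object, comp) {
  if (is.null(dim(comp))) comp <- matrix(comp, nrow = 1,
                                         dimnames = list(NULL, names(comp)))
  object$intercept + as.vector(comp[, AA_ALPHABET20, drop = FALSE] %*%
                                 object$weights)
}

#' Degron probability of 17-mer peptides
#'
#' @param object A `degron_model`.
#' @param sequences Character vector of 17-mers. Longer peptides must go
#'   through [region_score()], which averages over their 17-mer windows.
#' @param ... Ignored.
#' @return Numeric vector of degron probabilities in (0, 1).
#' @export
predict.degron_model <- function(object, sequences, ...) {
  if (any(nchar(sequences) != 17L))
    stop("predict() scores 17-mers only; use region_score() for longer ",
         "peptides", call. = FALSE)
  sigmoid(.model_eta(object, aa_composition(sequences)))
}

#' Average degron probability of a peptide of length >= 17
#'
#' The mean probability over all `L - 16` constituent 17-mer windows; for a
#' 23-mer that is the mean of 7 window scores. Reduces to a single-window
#' prediction at length 17.
#'
#' @param model A `degron_model`.
#' @param sequence Amino-acid string, length >= 17.
#' @return The mean window probability.
#' @export
region_score <- function(model, sequence) {
  L <- nchar(sequence)
  if (L < 17L) stop("region_score needs length >= 17", call. = FALSE)
  starts <- seq_len(L - 16L)
  mean(predict(model, substring(sequence, starts, starts + 16L)))
}

#' Scan a protein for degron regions
#'
#' Scores every 17-mer window and assigns each window's probability to its
#' center residue (the 9th of 17), so the per-residue track is defined for
#' residues 9..L-8 and `NA` within 8 residues of either terminus (no value
#' is extrapolated to the termini). Maximal runs of center residues at or
#' above `cutoff` are called degron regions; each region is reported both as
#' the center-run (`start`, `end`) and as its full tile extent
#' (`tile_start = start - 8`, `tile_end = end + 8`). The region center is
#' `floor((start + end) / 2)` (ties resolve to the N-terminal side).
#'
#' @param model A `degron_model`.
#' @param sequence Protein sequence (length >= 17).
#' @param protein_id Optional id carried into the profile.
#' @param cutoff Degron probability cutoff (default 0.85).
#' @param comparator `"ge"` (default, `>=`) or `"gt"`.
#' @return A `degron_profile`: list with `protein_id`, `length`,
#'   `probability` (length-L numeric, NA at termini), and `regions` tibble
#'   (`start`, `end`, `tile_start`, `tile_end`, `center`, `max_prob`).
#' @export
scan_protein <- function(model, sequence, protein_id = NA_character_,
                         cutoff = 0.85, comparator = c("ge", "gt")) {
  comparator <- match.arg(comparator)
  L <- nchar(sequence)
  if (L < 17L)
    stop(sprintf("protein%s of length %d is shorter than the 17-residue ",
                 if (is.na(protein_id)) "" else paste0(" '", protein_id, "'"),
                 L), " scan window", call. = FALSE)
  starts <- seq_len(L - 16L)
  probs <- predict(model, substring(sequence, starts, starts + 16L))
  track <- rep(NA_real_, L)
  track[starts + 8L] <- probs
  hit <- if (comparator == "ge") probs >= cutoff else probs > cutoff
  regions <- tibble::tibble(start = integer(), end = integer(),
                            tile_start = integer(), tile_end = integer(),
                            center = integer(), max_prob = numeric())
  if (any(hit)) {
    r <- rle(hit)
    ends <- cumsum(r$lengths)
    begins <- ends - r$lengths + 1L
    runs <- which(r$values)
    cs <- starts[begins[runs]] + 8L   # center residue coords
    ce <- starts[ends[runs]] + 8L
    mx <- vapply(runs, function(k)
      max(probs[begins[k]:ends[k]]), numeric(1))
    regions <- tibble::tibble(
      start = as.integer(cs), end = as.integer(ce),
      tile_start = as.integer(cs - 8L), tile_end = as.integer(ce + 8L),
      center = as.integer(floor((cs + ce) / 2)),
      max_prob = mx)
  }
  structure(list(protein_id = protein_id, length = L, probability = track,
                 regions = regions, cutoff = cutoff,
                 comparator = comparator),
            class = "degron_profile")
}

#' @export
print.degron_profile <- function(x, ...) {
  cat(sprintf("degron profile%s: %d residues, %d region(s) at P %s %.2f\n",
              if (is.na(x$protein_id)) "" else paste0(" for ", x$protein_id),
              x$length, nrow(x$regions),
              if (x$comparator == "ge") ">=" else ">", x$cutoff))
  if (nrow(x$regions)) print(x$regions)
  invisible(x)
}

#' Correlate model weights with the Kyte-Doolittle hydropathy scale
#'
#' @param model A `degron_model`.
#' @return List with `pearson`, `spearman`, and `table` (amino acid, weight,
#'   Kyte-Doolittle value) for plotting.
#' @export
weight_hydrophobicity_correlation <- function(model) {
  tab <- tibble::tibble(aa = AA_ALPHABET20,
                        weight = unname(model$weights[AA_ALPHABET20]),
                        kd = unname(KYTE_DOOLITTLE[AA_ALPHABET20]))
  list(pearson = stats::cor(tab$weight, tab$kd),
       spearman = stats::cor(tab$weight, tab$kd, method = "spearman"),
       table = tab)
}

#' Score a peptide before and after point substitutions
#'
#' Utility for mutagenesis-style analyses, e.g. suppressing a degron by
#' replacing hydrophobic residues with glutamate or arginine.
#'
#' @param model A `degron_model`.
#' @param sequence 17-mer peptide.
#' @param positions Integer positions (1-based) to replace.
#' @param replacement A single amino-acid letter.
#' @return Named numeric `c(before =, after =)` probabilities; the mutant
#'   sequence is attached as attribute `"mutant"`.
#' @export
mutate_and_rescore <- function(model, sequence, positions, replacement) {
  chars <- .check_sequence(sequence)
  if (!replacement %in% AA_ALPHABET20)
    stop("replacement must be a single standard amino acid", call. = FALSE)
  if (any(positions < 1L | positions > length(chars)))
    stop("position out of range", call. = FALSE)
  mutant <- chars
  mutant[positions] <- replacement
  mutant <- paste(mutant, collapse = "")
  out <- c(before = predict(model, sequence),
           after = predict(model, mutant))
  attr(out, "mutant") <- mutant
  out
}

#' Write a degron model to JSON
#'
#' Stores the 20 named weights together with the feature convention,
#' regularization and training-set digest.
#'
#' @param model A `degron_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_degron_model <- function(model, path) {
  jsonlite::write_json(list(
    weights = as.list(model$weights),
    intercept = model$intercept,
    lambda = model$lambda,
    feature = model$feature,
    n_unstable = model$n_unstable,
    n_stable = model$n_stable,
    training_digest = model$training_digest
  ), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a degron model written by [write_degron_model()]
#'
#' @param path JSON path.
#' @return A `degron_model`.
#' @export
read_degron_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- degron_model(unlist(j$weights), intercept = j$intercept %||% 0)
  m$lambda <- j$lambda %||% NA_real_
  m$n_unstable <- j$n_unstable %||% NA_integer_
  m$n_stable <- j$n_stable %||% NA_integer_
  m$training_digest <- j$training_digest %||% NA_character_
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a scan profile to per-residue and region TSVs
#'
#' @param profile A `degron_profile`.
#' @param residue_path TSV for the per-residue track (protein_id,
#'   residue_index, probability; rows limited to defined residues).
#' @param region_path TSV for called regions (1-based inclusive
#'   coordinates).
#' @return Invisibly, the two paths.
#' @export
write_profile <- function(profile, residue_path, region_path) {
  defined <- which(!is.na(profile$probability))
  utils::write.table(
    data.frame(protein_id = profile$protein_id, residue_index = defined,
               probability = profile$probability[defined]),
    residue_path, sep = "\t", quote = FALSE, row.names = FALSE)
  regions <- cbind(protein_id = profile$protein_id,
                   as.data.frame(profile$regions))
  utils::write.table(regions, region_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(residue_path, region_path))
}
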