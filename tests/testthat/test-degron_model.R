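kd_model <- degron_model(KYTE_DOOLITTLE)

test_that("training recovers known weights from Bernoulli-labelled compositions", {
  set.seed(31)
  n <- 20000
  seqs <- random_peptide(n)
  comp <- aa_composition(seqs)
  truth <- KYTE_DOOLITTLE
  p <- 1 / (1 + exp(-as.vector(comp %*% truth)))
  labels <- rbinom(n, 1, p)
  model <- train_degron_model(seqs, labels)
  expect_length(model$weights, 20)
  expect_gte(cor(unname(model$weights), unname(truth)), 0.95)
})

test_that("uninformative labels shrink weights relative to informative ones", {
  set.seed(32)
  n <- 4000
  seqs <- random_peptide(n)
  comp <- aa_composition(seqs)
  p <- 1 / (1 + exp(-as.vector(comp %*% KYTE_DOOLITTLE)))
  informative <- train_degron_model(seqs, rbinom(n, 1, p))
  null <- train_degron_model(seqs, rbinom(n, 1, 0.5))
  expect_lt(max(abs(null$weights)), max(abs(informative$weights)))
})

test_that("the fit depends on the empirical distribution, not the sample size", {
  set.seed(33)
  seqs <- random_peptide(500)
  labels <- rbinom(500, 1, 0.5 + 0.3 * (gravy(seqs) > 0))
  m1 <- train_degron_model(seqs, labels, lambda = 0.01)
  m2 <- train_degron_model(rep(seqs, 2), rep(labels, 2), lambda = 0.01)
  expect_equal(m1$weights, m2$weights, tolerance = 1e-8)
})

test_that("training rejects degenerate inputs", {
  seqs <- random_peptide(10)
  expect_error(train_degron_model(seqs, rep(1, 10)), "single class")
  expect_error(train_degron_model(random_peptide(4, len = 12),
                                  c(0, 1, 0, 1)), "17-mers")
  expect_error(train_degron_model(seqs, c(0, 1)), "differ in length")
})

test_that("in-package ridge fit matches glmnet on the same objective", {
  skip_if_not_installed("glmnet")
  set.seed(34)
  n <- 3000
  seqs <- random_peptide(n)
  comp <- aa_composition(seqs)
  p <- 1 / (1 + exp(-as.vector(comp %*% KYTE_DOOLITTLE)))
  y <- rbinom(n, 1, p)
  lam <- 0.01
  mine <- train_degron_model(seqs, y, lambda = lam)
  ref <- glmnet::glmnet(comp, y, family = "binomial", alpha = 0,
                        lambda = lam, intercept = FALSE,
                        standardize = FALSE, thresh = 1e-12)
  expect_equal(unname(mine$weights),
               as.vector(ref$beta)[match(AA_ALPHABET20, rownames(ref$beta))],
               tolerance = 1e-3)
})

test_that("prediction is a permutation-invariant sigmoid of composition", {
  expect_equal(predict(degron_model(rep(0, 20)), "YLVPFIIAAMVIMHLMA"), 0.5)
  tab <- table1_peptides()
  p1 <- tab$sequence[tab$name == "P1"]
  sc1 <- tab$sequence[tab$name == "SC1"]
  sc2 <- tab$sequence[tab$name == "SC2"]
  expect_identical(predict(kd_model, p1), predict(kd_model, sc1))
  expect_identical(predict(kd_model, p1), predict(kd_model, sc2))
  expect_error(predict(kd_model, "ACDEF"), "17-mers")
})

test_that("probability is monotone in the fraction of high-weight residues", {
  # replace a negative-weight residue (D) by a positive-weight one (I)
  s <- paste0(strrep("D", 8), strrep("I", 9))
  s_up <- paste0(strrep("D", 7), strrep("I", 10))
  expect_gt(predict(kd_model, s_up), predict(kd_model, s))
})

test_that("scan assigns window scores to center residues and calls regions", {
  # single-window protein: one defined residue at position 9
  prof <- scan_protein(kd_model, strrep("I", 17), "poly")
  expect_equal(which(!is.na(prof$probability)), 9L)
  expect_equal(nrow(prof$regions), 1L)
  expect_equal(prof$regions$start, 9L)
  expect_equal(prof$regions$tile_start, 1L)
  expect_equal(prof$regions$tile_end, 17L)

  # homopolymer: flat profile
  prof2 <- scan_protein(kd_model, strrep("L", 40))
  defined <- prof2$probability[!is.na(prof2$probability)]
  expect_length(defined, 40 - 16)
  expect_true(all(defined == defined[1]))

  expect_error(scan_protein(kd_model, strrep("A", 10)), "shorter")
})

test_that("scan regions match a brute-force window enumeration", {
  # hydrophilic flanks around a hydrophobic core
  seqn <- paste0(strrep("D", 12), strrep("I", 16), strrep("K", 12))
  prof <- scan_protein(kd_model, seqn, cutoff = 0.85)
  # oracle: score every window explicitly and find runs by hand
  L <- nchar(seqn)
  starts <- 1:(L - 16)
  probs <- vapply(starts, function(st) {
    comp <- aa_composition(substr(seqn, st, st + 16))
    1 / (1 + exp(-sum(comp * KYTE_DOOLITTLE)))
  }, numeric(1))
  hit_centers <- (starts + 8)[probs >= 0.85]
  expect_equal(nrow(prof$regions), 1L)
  expect_equal(prof$regions$start, min(hit_centers))
  expect_equal(prof$regions$end, max(hit_centers))
  expect_equal(prof$regions$center,
               as.integer(floor((min(hit_centers) + max(hit_centers)) / 2)))
  expect_equal(prof$regions$max_prob, max(probs))
  expect_equal(prof$probability[starts + 8], probs)
})

test_that("region_score averages all constituent 17-mer windows", {
  s17 <- random_peptide(len = 17)
  expect_equal(region_score(kd_model, s17), predict(kd_model, s17))
  s23 <- random_peptide(len = 23)
  manual <- mean(vapply(1:7, function(st)
    predict(kd_model, substr(s23, st, st + 16)), numeric(1)))
  expect_equal(region_score(kd_model, s23), manual)
  # homopolymer: every window identical
  expect_equal(region_score(kd_model, strrep("V", 20)),
               predict(kd_model, strrep("V", 17)))
  expect_error(region_score(kd_model, "SHORT"), "17")
})

test_that("weight-hydropathy correlation is exact for scale-equal weights", {
  expect_equal(weight_hydrophobicity_correlation(kd_model)$pearson, 1)
  neg <- degron_model(-KYTE_DOOLITTLE)
  expect_equal(weight_hydrophobicity_correlation(neg)$pearson, -1)
  expect_equal(weight_hydrophobicity_correlation(neg)$spearman, -1)
})

test_that("mutate_and_rescore reflects composition deltas exactly", {
  s <- "FKRNAVFVGTIFAGAFV"
  noop <- mutate_and_rescore(kd_model, s, 1, "F")
  expect_equal(unname(noop["before"]), unname(noop["after"]))
  # glutamate has a negative weight: replacing 3 residues lowers the score
  mut <- mutate_and_rescore(kd_model, s, c(11, 12, 16), "E")
  expect_lt(unname(mut["after"]), unname(mut["before"]))
  expect_equal(attr(mut, "mutant"), "FKRNAVFVGTEEAGAEV")
  # arithmetic oracle on a toy 2-weight model
  w <- setNames(rep(0, 20), AA_ALPHABET20)
  w["A"] <- 2; w["C"] <- -1
  toy <- degron_model(w)
  s2 <- paste0(strrep("A", 10), strrep("C", 7))
  out <- mutate_and_rescore(toy, s2, 1, "C")
  expect_equal(unname(out["before"]), 1 / (1 + exp(-(2 * 10 / 17 - 7 / 17))))
  expect_equal(unname(out["after"]), 1 / (1 + exp(-(2 * 9 / 17 - 8 / 17))))
  expect_error(mutate_and_rescore(toy, s2, 40, "A"), "range")
})

test_that("models round-trip through the JSON file format", {
  path <- tempfile(fileext = ".json")
  write_degron_model(kd_model, path)
  back <- read_degron_model(path)
  expect_equal(back$weights, kd_model$weights)
  s <- random_peptide(len = 17)
  expect_equal(predict(back, s), predict(kd_model, s))
})

test_that("acidic residues dominate the stable class under a charge penalty truth", {
  set.seed(35)
  truth <- KYTE_DOOLITTLE
  truth[c("D", "E")] <- truth[c("D", "E")] - 2  # extra charge penalty
  n <- 15000
  seqs <- random_peptide(n)
  comp <- aa_composition(seqs)
  p <- 1 / (1 + exp(-as.vector(comp %*% truth)))
  model <- train_degron_model(seqs, rbinom(n, 1, p))
  ranks <- rank(model$weights)
  expect_true(all(ranks[c("D", "E")] <= 3))
})
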