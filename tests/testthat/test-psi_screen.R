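test_that("normalize_gates divides by per-gate sequencing depth", {
  # depths (100, 200, 100, 100) built from two peptides
  counts <- make_counts(c("a", "b"),
                        c(10, 20, 0, 0,
                          90, 180, 100, 100))
  f <- normalize_gates(counts)
  expect_equal(unlist(f[1, paste0("f", 1:4)], use.names = FALSE),
               c(0.1, 0.1, 0, 0))
  expect_equal(unname(attr(f, "gate_totals")), c(100, 200, 100, 100))

  expect_error(normalize_gates(make_counts("a", rep(0, 4))), "zero")
  # a gate with zero total yields zero frequencies, not NaN
  g0 <- normalize_gates(make_counts(c("a", "b"), c(1, 0, 2, 3, 1, 0, 2, 3)))
  expect_equal(g0$f2, c(0, 0))
})

test_that("compute_psi implements the gate-weighted frequency mean", {
  # the balancer row equalizes gate depths so counts equal frequencies
  counts <- make_counts(c("lo", "hi", "even", "mix", "balancer"),
                        c(40, 0, 0, 0,
                          0, 0, 0, 40,
                          10, 10, 10, 10,
                          10, 0, 0, 30,
                          40, 90, 90, 20))
  psi <- compute_psi(counts)
  expect_equal(psi$psi[psi$peptide_id == "lo"], 1)
  expect_equal(psi$psi[psi$peptide_id == "hi"], 4)
  expect_equal(psi$psi[psi$peptide_id == "even"], 2.5)
  expect_equal(psi$psi[psi$peptide_id == "mix"], 0.25 * 1 + 0.75 * 4)
  expect_true(all(psi$psi >= 1 & psi$psi <= 4))
})

test_that("compute_psi agrees with a brute-force oracle on random tables", {
  set.seed(99)
  counts <- make_counts(sprintf("p%04d", 1:1000),
                        rpois(4000, lambda = 20))
  psi <- suppressMessages(compute_psi(counts))
  # independent oracle: explicit per-row frequency loop
  m <- as.matrix(counts[, c("G1", "G2", "G3", "G4")])
  totals <- colSums(m)
  oracle <- vapply(seq_len(nrow(m)), function(i) {
    f <- m[i, ] / totals
    sum((1:4) * f) / sum(f)
  }, numeric(1))
  expect_equal(psi$psi,
               unname(oracle[match(psi$peptide_id, counts$peptide_id)]),
               tolerance = 1e-12)
})

test_that("PSI is depth invariant and monotone in read mass", {
  counts <- make_counts(c("a", "b"), c(5, 10, 3, 2, 8, 1, 6, 9))
  base <- suppressMessages(compute_psi(counts))
  # multiply one gate's counts by a positive constant: frequencies unchanged
  scaled <- counts
  scaled$G2 <- scaled$G2 * 7L
  expect_equal(suppressMessages(compute_psi(scaled))$psi, base$psi)
  # moving reads from a lower to a higher gate never decreases PSI
  set.seed(3)
  for (i in 1:20) {
    cts <- rpois(4, 30) + 1
    one <- make_counts("x", cts)
    moved <- cts
    moved[1] <- moved[1] - 1L; moved[4] <- moved[4] + 1L
    two <- make_counts("x", moved)
    expect_gte(compute_psi(two)$psi, compute_psi(one)$psi)
  }
})

test_that("low-coverage filter keeps strictly more than min_reads", {
  counts <- make_counts(c("kept", "edge", "low"),
                        c(13, 13, 13, 12,    # 51 reads
                          50, 0, 0, 0,       # exactly 50
                          10, 10, 10, 10))   # 40
  expect_equal(filter_low_coverage(counts, 50)$peptide_id, "kept")
  expect_setequal(filter_low_coverage(counts, 0)$peptide_id,
                  c("kept", "edge", "low"))
})

test_that("training labels use the 2.2/2.8 PSI band and drop the middle", {
  psi <- make_psi_table(c("u", "s", "mid"), c(1.39, 3.25, 2.5))
  lab <- label_for_training(psi)
  expect_equal(lab$label[lab$peptide_id == "u"], "unstable")
  expect_equal(lab$label[lab$peptide_id == "s"], "stable")
  expect_false("mid" %in% lab$peptide_id)
  expect_error(label_for_training(psi, 2.8, 2.2), "below")
})

test_that("degron calls are strict at the cutoff and match the uniform fraction", {
  psi <- make_psi_table(c("deg", "edge", "stable"), c(1.44, 1.7, 3.0))
  res <- call_degrons(psi, cutoff = 1.7)
  expect_setequal(res$ids, "deg")
  res_le <- call_degrons(psi, cutoff = 1.7, comparator = "le")
  expect_setequal(res_le$ids, c("deg", "edge"))
  # under PSI ~ U(1,4) the sub-1.7 fraction is 0.7/3
  set.seed(11)
  u <- make_psi_table(sprintf("p%05d", 1:50000), runif(50000, 1, 4))
  expect_equal(call_degrons(u, 1.7)$fraction, 0.7 / 3, tolerance = 0.01)
})

test_that("delta-PSI thresholds and stabilization calls follow mean + 2 SE", {
  ids <- sprintf("d%02d", 1:5)
  ctrl <- make_psi_table(ids, rep(1.5, 5))
  dpsi <- c(0.1, -0.2, 0.05, 0.3, -0.05)
  ko <- make_psi_table(ids, 1.5 + dpsi)
  res <- delta_psi_analysis(ctrl, list(e3 = ko))$e3
  expect_equal(res$threshold, mean(dpsi) + 2 * sd(dpsi) / sqrt(5))
  expect_setequal(res$stabilized, ids[dpsi > res$threshold])
  # the 2-sd alternative
  res_sd <- delta_psi_analysis(ctrl, list(e3 = ko), se_method = "sd")$e3
  expect_equal(res_sd$threshold, mean(dpsi) + 2 * sd(dpsi))

  # control vs control: no stabilization
  null <- delta_psi_analysis(ctrl, list(self = ctrl))$self
  expect_equal(null$table$delta_psi, rep(0, 5))
  expect_length(null$stabilized, 0)

  expect_error(delta_psi_analysis(make_psi_table(ids[1:2], c(1, 1)),
                                  list(e3 = ko)), "fewer than 3")
})

test_that("spiked stabilization is recovered by the mean + 2 SE rule", {
  set.seed(21)
  n_null <- 2000; n_spike <- 100
  ids <- sprintf("p%04d", seq_len(n_null + n_spike))
  ctrl <- make_psi_table(ids, rep(1.4, n_null + n_spike))
  dpsi <- c(rnorm(n_null, 0, 0.1), rnorm(n_spike, 1.0, 0.1))
  ko <- make_psi_table(ids, 1.4 + dpsi)
  res <- delta_psi_analysis(ctrl, list(ko = ko))$ko
  spiked <- ids[(n_null + 1):(n_null + n_spike)]
  recovered <- mean(spiked %in% res$stabilized)
  expect_gte(recovered, 0.95)
  # false positives match the null exceedance probability of the threshold
  fpr <- sum(ids[1:n_null] %in% res$stabilized) / n_null
  expected_fpr <- pnorm(res$threshold, 0, 0.1, lower.tail = FALSE)
  expect_equal(fpr, expected_fpr, tolerance = 0.05)
})

test_that("top-fraction E3 overlap counts behave on identity, disjoint and random sets", {
  fake_result <- function(ids, dpsi)
    structure(list(table = tibble::tibble(peptide_id = ids,
                                          delta_psi = dpsi)),
              class = "delta_psi_result")
  ids <- sprintf("p%04d", 1:100)
  # identical rankings: the full top set is shared by all strains
  same <- fake_result(ids, seq_along(ids))
  ov <- e3_overlap(list(a = same, b = same, c = same), 0.10)
  expect_equal(unname(ov$region_counts["a&b&c"]), 10L)
  expect_equal(ov$fraction_multi, 1)

  # opposite rankings: pairwise intersections empty
  ov2 <- e3_overlap(list(a = fake_result(ids, seq_along(ids)),
                         b = fake_result(ids, rev(seq_along(ids)))), 0.10)
  expect_length(intersect(ov2$top_sets$a, ov2$top_sets$b), 0)
  expect_equal(ov2$fraction_multi, 0)

  # random rankings: pairwise overlap matches the hypergeometric expectation
  n <- 2175; k <- ceiling(0.10 * n)
  expect_equal(k, 218)
  ids_big <- sprintf("q%04d", 1:n)
  set.seed(5)
  overlaps <- replicate(100, {
    ov3 <- e3_overlap(list(a = fake_result(ids_big, sample(n)),
                           b = fake_result(ids_big, sample(n))), 0.10)
    length(intersect(ov3$top_sets$a, ov3$top_sets$b))
  })
  expect_equal(mean(overlaps), k^2 / n, tolerance = 0.1)
})

test_that("gate-count and PSI tables round-trip through TSV", {
  counts <- make_counts(c("a", "b"), c(60, 1, 2, 3, 4, 70, 5, 6),
                        sequences = random_peptide(2))
  path <- tempfile(fileext = ".tsv")
  utils::write.table(counts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  back <- read_gate_counts(path, strain = "ctrl")
  expect_equal(attr(back, "strain"), "ctrl")
  expect_equal(back$G1, counts$G1)

  psi <- compute_psi(back)
  p2 <- tempfile(fileext = ".tsv")
  write_psi(psi, p2)
  again <- read_psi(p2)
  expect_equal(again$psi, psi$psi)
})

test_that("ambiguous sequences mapping to several members are dropped on read", {
  counts <- make_counts(c("a", "b", "c"),
                        c(60, 1, 2, 3, 4, 70, 5, 6, 7, 8, 60, 9),
                        sequences = c("AAAAA", "AAAAA", "CCCCC"))
  path <- tempfile(fileext = ".tsv")
  utils::write.table(counts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_message(back <- read_gate_counts(path), "ambiguous")
  expect_equal(back$peptide_id, "c")
})
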