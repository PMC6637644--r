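test_that("log2_ratios transforms and guards its domain", {
  tab <- make_table(c(1.0, 171.5, 0.52))
  lt <- log2_ratios(tab)
  expect_equal(lt$log2_ratio[1], 0)
  expect_equal(lt$log2_ratio[2], 7.422, tolerance = 1e-3)
  expect_equal(lt$log2_ratio[3], -0.943, tolerance = 1e-3)

  bad <- make_table(c(1, NA, 2))
  expect_error(log2_ratios(bad), "P002")
})

test_that("population_stats uses the sample SD and matches hand arithmetic", {
  s <- population_stats(c(0, 0, 0, 0))
  expect_equal(c(s$mean_log2, s$sd_log2, s$n), c(0, 0, 4))

  s <- population_stats(c(0, 0, 0, 0, 4))
  expect_equal(s$mean_log2, 0.8)
  expect_equal(s$sd_log2, sqrt(12.8 / 4))  # n-1 convention, SS = 12.8

  expect_error(population_stats(1), "at least 2")
  expect_error(population_stats(c(0, Inf)), "finite")

  # mean(log2 x) = log2(geometric mean of raw ratios)
  set.seed(41)
  r <- exp(rnorm(200))
  s <- population_stats(log2(r))
  expect_equal(s$mean_log2, log2(exp(mean(log(r)))), tolerance = 1e-12)

  # robust mode is insensitive to one extreme spike
  x <- c(rnorm(500), 7.4)
  expect_lt(abs(population_stats(log2(2^x), robust = TRUE)$sd_log2 -
                population_stats(x[-501])$sd_log2), 0.2)
})

test_that("z_scores standardizes exactly and rejects degenerate populations", {
  pop <- c(0, 0, 0, 0, 4)
  lt <- data.frame(accession = sprintf("P%d", 1:5), log2_ratio = pop)
  st <- population_stats(pop)
  zt <- z_scores(lt, st)
  expect_equal(zt$z[5], (4 - 0.8) / sqrt(12.8 / 4), tolerance = 1e-12)
  expect_equal(zt$z[1], (0 - 0.8) / sqrt(12.8 / 4), tolerance = 1e-12)
  # a value at the mean scores zero
  zt0 <- z_scores(data.frame(accession = "x", log2_ratio = st$mean_log2), st)
  expect_equal(zt0$z, 0)
  # standardization identity
  expect_equal(mean(zt$z), 0, tolerance = 1e-9)
  expect_equal(sd(zt$z), 1, tolerance = 1e-9)

  flat <- population_stats(c(1, 1, 1))
  expect_error(z_scores(lt, flat), "degenerate")
})

test_that("z_scores agrees with element-wise brute-force computation", {
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(5:2000, 1)
    pop <- rnorm(n, sd = runif(1, 0.1, 3)) + runif(1, -2, 2)
    lt <- data.frame(accession = as.character(seq_len(n)), log2_ratio = pop)
    z <- z_scores(lt, population_stats(pop))$z
    m <- sum(pop) / n
    s <- sqrt(sum((pop - m)^2) / (n - 1))
    oracle <- vapply(pop, function(v) (v - m) / s, numeric(1))
    expect_equal(z, oracle, tolerance = 1e-12)
  }
})

test_that("classification applies the dual criterion with printed strictness", {
  th <- silac_thresholds()
  cls <- function(l2, z) unlist(classify_regulation(l2, z, th))
  expect_equal(cls(0, 0), c(direction = "unchanged", tier = "none"))
  # fold criterion is strict ">": exactly 0.58 does not pass
  expect_equal(cls(0.58, 3.0), c(direction = "unchanged", tier = "none"))
  # z criterion is inclusive ">=": exactly 1.960 passes
  expect_equal(cls(0.60, 1.960), c(direction = "up", tier = "ci95"))
  expect_equal(cls(7.42, 5.0), c(direction = "up", tier = "ci999"))
  expect_equal(cls(-0.943, -2.1), c(direction = "down", tier = "ci95"))
  # sign consistency: a down fold with a positive z is contradictory
  expect_equal(cls(-1.0, 3.0), c(direction = "unchanged", tier = "none"))
  expect_equal(cls(1.0, -3.0), c(direction = "unchanged", tier = "none"))
  # tier boundaries
  expect_equal(cls(1, 2.576), c(direction = "up", tier = "ci99"))
  expect_equal(cls(1, 3.291), c(direction = "up", tier = "ci999"))
})

test_that("default thresholds satisfy their ordering invariants", {
  expect_error(silac_thresholds(z_cut = 3), "z_cut")
  expect_error(silac_thresholds(log2_cut = 0), "log2_cut")
  expect_error(silac_thresholds(fold_down = 1.2), "fold_down")
})

test_that("calls are monotone in z and equivariant under ratio rescaling", {
  th <- silac_thresholds()
  # monotonicity: for fixed log2 ratio above the cut, growing z never
  # demotes an up call, and tiers are monotone in |z|
  zs <- seq(1.96, 6, by = 0.25)
  out <- classify_regulation(rep(1, length(zs)), zs, th)
  expect_true(all(out$direction == "up"))
  expect_true(all(diff(match(out$tier, c("none", "ci95", "ci99", "ci999"))) >= 0))

  # rescaling every raw ratio by c shifts log2 by log2(c), z unchanged
  set.seed(11)
  ratios <- 2^rnorm(300)
  t1 <- make_table(ratios)
  t2 <- make_table(ratios * 3.7)
  z1 <- replicate_calls(t1, th)
  z2 <- replicate_calls(t2, th)
  expect_equal(z2$z, z1$z, tolerance = 1e-9)
  expect_equal(z2$log2_ratio - z1$log2_ratio,
               rep(log2(3.7), 300), tolerance = 1e-9)
})

test_that("combine_replicates requires agreement in both replicates", {
  r1 <- make_calls(c("A", "B", "C", "D", "E"),
                   c(4.0, 3.0, 0.4, 2.5, 1.0),
                   c("up", "up", "down", "up", "unchanged"),
                   tier = c("ci999", "ci95", "ci99", "ci95", "none"))
  r2 <- make_calls(c("A", "B", "C", "D", "E"),
                   c(3.5, 1.1, 0.5, 0.3, 1.0),
                   c("up", "unchanged", "down", "down", "unchanged"),
                   tier = c("ci99", "none", "ci999", "ci99", "none"))
  out <- combine_replicates(list(r1, r2))
  final <- setNames(out$direction, out$accession)
  expect_equal(final[["A"]], "up")          # up + up
  expect_equal(final[["B"]], "unchanged")   # up + unchanged
  expect_equal(final[["C"]], "down")        # down + down
  expect_equal(final[["D"]], "unchanged")   # up + down conflict
  expect_equal(final[["E"]], "unchanged")

  # average ratio is the geometric mean; combined tier the weaker one
  expect_equal(out$average_ratio[out$accession == "A"], sqrt(4.0 * 3.5))
  expect_equal(out$tier[out$accession == "A"], "ci99")
  expect_equal(out$tier[out$accession == "C"], "ci99")
  expect_equal(out$tier[out$accession == "B"], "none")

  # protein present in only one replicate is never called
  r3 <- make_calls("F", 5.0, "up")
  out2 <- combine_replicates(list(rbind(r1, r3), r2))
  expect_equal(out2$direction[out2$accession == "F"], "unchanged")
  expect_true(is.na(out2$average_ratio[out2$accession == "F"]))

  expect_error(combine_replicates(list(r1)), "exactly 2")
  expect_error(combine_replicates(list(r1, r2, r1)), "exactly 2")
})

test_that("combined up/down sets are subsets of each replicate's sets", {
  set.seed(23)
  for (i in 1:5) {
    sim <- simulate_experiment(simulation_config(
      n_proteins = 800, frac_up = 0.05, frac_down = 0.05,
      effect_log2_mean = 1.5, effect_log2_sd = 0.5, missing_rate = 0.05,
      contaminant_rate = 0, reverse_rate = 0, seed = i))
    per <- lapply(sim$tables, function(t)
      replicate_calls(suppressMessages(filter_quality(t))))
    out <- combine_replicates(per)
    for (d in c("up", "down")) {
      comb <- out$accession[out$direction == d]
      for (p in per) {
        expect_true(all(comb %in% p$accession[p$direction == d]))
      }
    }
  }
})

test_that("rank_top orders by average ratio with accession tie-breaks", {
  calls <- data.frame(
    accession = c("P3", "P1", "P2", "P5", "P4", "P6"),
    gene_name = letters[1:6],
    direction = c("up", "up", "up", "down", "down", "unchanged"),
    average_ratio = c(3, 4, 2, 0.4, 0.2, 1.0),
    stringsAsFactors = FALSE)
  top2 <- rank_top(calls, "up", 2)
  expect_equal(top2$average_ratio, c(4, 3))
  expect_equal(rank_top(calls, "down", 10)$average_ratio, c(0.2, 0.4))
  expect_equal(nrow(rank_top(calls, "up", 100)), 3L)

  tied <- data.frame(accession = c("PB", "PA"), gene_name = c("b", "a"),
                     direction = "up", average_ratio = c(2, 2),
                     stringsAsFactors = FALSE)
  expect_equal(rank_top(tied, "up", 2)$accession, c("PA", "PB"))
})

test_that("the per-replicate rule holds its nominal null error rate", {
  # i.i.d. normal null log2 ratios, sd 1 so the fold criterion binds rarely:
  # per-replicate flagged fraction ~5%, both-replicate intersection <=1%
  n <- 5000
  per_rep <- both <- numeric(20)
  for (s in 1:20) {
    sim <- simulate_experiment(simulation_config(
      n_proteins = n, frac_up = 0, frac_down = 0, null_sd_log2 = 1,
      missing_rate = 0, contaminant_rate = 0, reverse_rate = 0, seed = 100 + s))
    per <- lapply(sim$tables, function(t)
      replicate_calls(suppressMessages(filter_quality(t))))
    flagged <- vapply(per, function(p) mean(p$direction != "unchanged"),
                      numeric(1))
    per_rep[s] <- mean(flagged)
    out <- combine_replicates(per)
    both[s] <- mean(out$direction != "unchanged")
  }
  expect_lte(mean(per_rep), 0.055)
  expect_lte(mean(both), 0.01)
})
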