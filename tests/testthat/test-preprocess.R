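test_that("rarefy draws every retained sample to exact depth, seeded", {
  m <- matrix(rpois(5 * 3, 2000), 5, 3,
              dimnames = list(paste0("ASV_", 1:5), paste0("S", 1:3)))
  ct <- count_table(m, "nematode")
  out <- rarefy(ct, 412, seed = 9)
  expect_true(all(colSums(out$counts) == 412))
  expect_identical(out$counts, rarefy(ct, 412, seed = 9)$counts)

  # under-depth samples are dropped with a warning, not padded
  m2 <- m; m2[, 2] <- c(100L, 50L, 50L, 50L, 50L)
  expect_warning(out2 <- rarefy(count_table(m2, "nematode"), 412, seed = 1),
                 "dropping 1 sample")
  expect_equal(ncol(out2$counts), 2)
  expect_error(rarefy(ct, 0), "positive")
})

test_that("rarefaction depth equal to the sample total leaves counts unchanged", {
  m <- matrix(c(10L, 20L, 30L), 3, 1, dimnames = list(paste0("t", 1:3), "S1"))
  out <- rarefy(count_table(m, "protist"), 60, seed = 2)
  expect_equal(out$counts[, 1], m[, 1])
})

test_that("rarefy is unbiased: E[count] = depth * proportion (200 replicates)", {
  m <- matrix(c(500L, 300L, 100L, 80L, 20L), 5, 1,
              dimnames = list(paste0("t", 1:5), "S1"))
  ct <- count_table(m, "bacteria")
  depth <- 200
  reps <- sapply(1:200, function(s) rarefy(ct, depth, seed = s)$counts[, 1])
  expected <- depth * m[, 1] / sum(m)
  # hypergeometric variance for each taxon
  N <- sum(m); v <- depth * (m[, 1] / N) * (1 - m[, 1] / N) * (N - depth) / (N - 1)
  se <- sqrt(v / 200)
  expect_true(all(abs(rowMeans(reps) - expected) < 3 * se + 1e-9))
})

test_that("merge_domains concatenates with domain prefixes and checks samples", {
  mk <- function(n, domain, samples = paste0("S", 1:4)) {
    m <- matrix(rpois(n * length(samples), 5), n, length(samples),
                dimnames = list(paste0("ASV_", 1:n), samples))
    count_table(m, domain)
  }
  tabs <- list(mk(80, "bacteria"), mk(35, "fungi"), mk(13, "protist"), mk(2, "nematode"))
  merged <- merge_domains(tabs)
  expect_equal(nrow(merged$counts), 130)
  # shared raw ids cannot collide after prefixing
  expect_true(all(c("B_ASV_1", "F_ASV_1", "P_ASV_1", "N_ASV_1") %in%
                    rownames(merged$counts)))
  expect_error(merge_domains(list(tabs[[1]], mk(5, "fungi", paste0("S", 2:5)))),
               "S1|S5")
})

test_that("prevalence filter is strict and idempotent", {
  m <- matrix(0L, 3, 18, dimnames = list(c("t9", "t10", "t18"), paste0("S", 1:18)))
  m["t9", 1:9] <- 1L    # exactly 50%: must be removed
  m["t10", 1:10] <- 1L  # >50%: retained
  m["t18", ] <- 1L
  ct <- count_table(m, "bacteria")
  out <- prevalence_filter(ct, 0.5)
  expect_setequal(rownames(out$counts), c("t10", "t18"))
  expect_identical(prevalence_filter(out, 0.5)$counts, out$counts)
  # min_frac = 0 keeps anything detected at least once
  expect_equal(nrow(prevalence_filter(ct, 0)$counts), 3)
  expect_warning(prevalence_filter(subset_empty <- count_table(
    matrix(0L, 1, 4, dimnames = list("t", paste0("S", 1:4))), "fungi"), 0.5),
    "no taxon")
})

test_that("merging then per-group subsetting commutes with the reverse order", {
  samples <- paste0("S", 1:6)
  mk <- function(n, domain) {
    m <- matrix(rpois(n * 6, 5), n, 6,
                dimnames = list(paste0("ASV_", 1:n), samples))
    count_table(m, domain)
  }
  set.seed(42)
  tabs <- list(mk(6, "bacteria"), mk(4, "fungi"))
  grp <- samples[1:3]
  merged <- merge_domains(tabs)
  a <- mconet:::subset_samples(merged, colnames(merged$counts) %in% grp)
  b <- merge_domains(lapply(tabs, function(t)
    mconet:::subset_samples(t, colnames(t$counts) %in% grp)))
  expect_identical(a$counts, b$counts)
})

test_that("abundance transform fills zeros with the pseudo-count and is monotone", {
  m <- matrix(c(0L, 1L, 100L, 7L), 2, 2,
              dimnames = list(c("t1", "t2"), c("S1", "S2")))
  X <- transform_abundance(count_table(m, "fungi"), pseudo = 0.01)
  expect_equal(X["t1", "S1"], -2)
  expect_equal(X["t1", "S2"], 2)
  expect_error(transform_abundance(count_table(m, "fungi"), pseudo = 0), "positive")
  counts <- sample(0:50, 20, replace = TRUE)
  m2 <- matrix(as.integer(counts), 20, 1,
               dimnames = list(paste0("t", 1:20), "S1"))
  X2 <- transform_abundance(count_table(m2, "bacteria"))[, 1]
  expect_equal(order(X2), order(counts, seq_along(counts))) # ties keep order
})
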