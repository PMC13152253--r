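test_that("well-formed files parse to identical records", {
  df <- tibble::tibble(
    variant_id = c("rs1", "rs2", "rs3"), chromosome = c("1", "1", "2"),
    position = c(1000L, 2000L, 3000L),
    effect_allele = c("a", "C", "G"), other_allele = c("g", "T", "A"),
    eaf = c(0.1, 0.5, NA), beta = c(0.02, -0.03, 0), se = c(0.01, 0.02, 0.01),
    pvalue = c(1e-9, 0.04, 0.99), n = c(1e5, 1e5, 1e5)
  )
  x <- read_summary_stats(write_sumstat_file(df), trait = "bmi", scale = "sd")
  expect_s3_class(x, "mr_sumstats")
  expect_equal(nrow(x), 3)
  expect_equal(x$effect_allele, c("A", "C", "G")) # upper-cased
  expect_equal(x$beta, df$beta)
  expect_equal(attr(x, "trait"), "bmi")
  expect_equal(attr(x, "n_dropped"), 0L)
})

test_that("rows violating invariants are dropped and tallied", {
  df <- tibble::tibble(
    variant_id = c("rs1", "rs2", "rs3", "rs4", "rs5"),
    effect_allele = c("A", "A", "A", "A", "A"),
    other_allele = c("G", "G", "A", "G", "G"),
    beta = c(0.1, 0.1, 0.1, 0.1, 0.1),
    se = c(0.01, 0, 0.01, 0.01, 0.01),       # rs2: se = 0
    pvalue = c(0.01, 0.01, 0.01, 0, 1.5)     # rs4: p = 0, rs5: p > 1
  )                                          # rs3: identical alleles
  expect_warning(x <- as_sumstats(df), "dropped 4")
  expect_equal(x$variant_id, "rs1")
  expect_equal(attr(x, "n_dropped"), 4L)
})

test_that("missing mandatory columns and empty results are fatal", {
  df <- tibble::tibble(variant_id = "rs1", effect_allele = "A",
                       other_allele = "G", se = 0.01, pvalue = 0.5)
  expect_error(as_sumstats(df), "beta")
  bad <- tibble::tibble(variant_id = "rs1", effect_allele = "A",
                        other_allele = "G", beta = 0.1, se = 0, pvalue = 0.5)
  expect_error(suppressWarnings(as_sumstats(bad)), "no valid")
})

test_that("common column aliases are resolved", {
  df <- tibble::tibble(SNP = "rs1", chr = "1", bp = 100, A1 = "A", A2 = "G",
                       freq = 0.2, b = 0.1, SE = 0.01, pval = 1e-9,
                       N = 1000)
  x <- as_sumstats(df)
  expect_equal(x$variant_id, "rs1")
  expect_equal(x$position, 100L)
  expect_equal(x$eaf, 0.2)
  expect_equal(x$pvalue, 1e-9)
})

test_that("genome-wide selection keeps p < threshold, preserving order", {
  x <- make_sumstats(3, pvalue = c(1e-9, 1e-7, 1e-8))
  sel <- select_genome_wide(x, 5e-8)
  expect_equal(sel$variant_id, c("rs1", "rs3"))
  expect_warning(empty <- select_genome_wide(make_sumstats(2, pvalue = c(0.5, 0.5))),
                 "no variants")
  expect_equal(nrow(empty), 0)
  suppressWarnings(expect_equal(nrow(select_genome_wide(sel, 1e-20)), 0))
})

test_that("greedy clumping applies the p-ordered window-and-r2 rule", {
  x <- make_sumstats(
    3, pvalue = c(1e-10, 1e-9, 1e-8),
    position = c(1e6, 1.05e6, 2e6), variant_id = c("s1", "s2", "s3")
  )
  ld <- as_ld_table(tibble::tibble(
    variant_id_a = c("s1", "s1", "s2"), variant_id_b = c("s2", "s3", "s3"),
    r2 = c(0.9, 0, 0)
  ))
  expect_equal(clump_greedy(x, ld)$variant_id, c("s1", "s3"))
  # all pairwise r2 = 0 on one chromosome: everything kept
  ld0 <- as_ld_table(tibble::tibble(variant_id_a = "s1", variant_id_b = "s2",
                                    r2 = 0))
  expect_equal(nrow(clump_greedy(x, ld0)), 3)
  # high r2 but outside the 10,000 kb window: both kept
  far <- make_sumstats(2, pvalue = c(1e-10, 1e-9),
                       position = c(1e6, 1e6 + 2e10 / 1000),
                       variant_id = c("a", "b"))
  ldf <- as_ld_table(tibble::tibble(variant_id_a = "a", variant_id_b = "b",
                                    r2 = 0.9))
  expect_equal(nrow(clump_greedy(far, ldf, window_kb = 10000)), 2)
  # missing LD pair within the window counts as r2 = 0 (kept)
  expect_equal(nrow(clump_greedy(x, NULL)), 3)
  # unknown ids in the LD table are ignored with a warning
  ldu <- as_ld_table(tibble::tibble(variant_id_a = "zzz", variant_id_b = "s1",
                                    r2 = 0.5))
  expect_warning(clump_greedy(x, ldu), "unknown")
})

test_that("clumping output satisfies the exhaustive audit on random instances", {
  # every removed variant must have a kept variant within the window with
  # r2 above threshold; output is a subset in index order
  withr::with_seed(42, {
    for (rep in 1:5) {
      n <- 30
      x <- make_sumstats(
        n, pvalue = runif(n, 1e-12, 1e-6),
        chromosome = as.character(sample(1:2, n, TRUE)),
        position = sample.int(3e7, n),
        variant_id = sprintf("v%02d", 1:n)
      )
      pairs <- t(utils::combn(n, 2))
      keep_pair <- stats::runif(nrow(pairs)) < 0.3
      ld <- as_ld_table(tibble::tibble(
        variant_id_a = x$variant_id[pairs[keep_pair, 1]],
        variant_id_b = x$variant_id[pairs[keep_pair, 2]],
        r2 = stats::runif(sum(keep_pair))
      ))
      out <- clump_greedy(x, ld, r2_threshold = 0.1, window_kb = 5000)
      expect_true(all(out$variant_id %in% x$variant_id))
      r2m <- matrix(0, n, n, dimnames = list(x$variant_id, x$variant_id))
      r2m[cbind(ld$variant_id_a, ld$variant_id_b)] <- ld$r2
      r2m[cbind(ld$variant_id_b, ld$variant_id_a)] <- ld$r2
      removed <- setdiff(x$variant_id, out$variant_id)
      for (v in removed) {
        i <- match(v, x$variant_id)
        culprit <- vapply(out$variant_id, function(k) {
          j <- match(k, x$variant_id)
          x$chromosome[i] == x$chromosome[j] &&
            abs(x$position[i] - x$position[j]) <= 5000 * 1000 &&
            r2m[v, k] > 0.1 &&
            x$pvalue[j] < x$pvalue[i]
        }, logical(1))
        expect_true(any(culprit))
      }
    }
  })
})
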