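make_variant <- function(depth, alt_count, chrom_class = "autosome",
                         site = 1000L, repeat_flag = FALSE) {
  data.frame(site = site, ref = "C", alt = "T", depth = depth,
             alt_count = alt_count, chrom_class = chrom_class,
             repeat_flag = repeat_flag, stringsAsFactors = FALSE)
}

test_that("SNV thresholds match the published filter chain", {
  pol <- filter_policy()
  # depth below 20 removed even at perfect VAF
  expect_equal(nrow(filter_snvs(make_variant(19L, 10L), pol)$kept), 0L)
  # depth 40 / alt 20, no exclusions: kept at VAF 0.50
  expect_equal(nrow(filter_snvs(make_variant(40L, 20L), pol)$kept), 1L)
  # autosomal window is 35-65%
  expect_equal(nrow(filter_snvs(make_variant(40L, 13L), pol)$kept), 0L) # 0.325
  expect_equal(nrow(filter_snvs(make_variant(40L, 14L), pol)$kept), 1L) # 0.35
  expect_equal(nrow(filter_snvs(make_variant(40L, 26L), pol)$kept), 1L) # 0.65
  expect_equal(nrow(filter_snvs(make_variant(40L, 27L), pol)$kept), 0L) # 0.675
  # hemizygous sites need VAF >= 75%
  expect_equal(nrow(filter_snvs(make_variant(40L, 30L, "hemizygous"), pol)$kept), 1L)
  expect_equal(nrow(filter_snvs(make_variant(40L, 29L, "hemizygous"), pol)$kept), 0L)
  # two alt reads in the parental cells mean the variant is shared
  par1 <- data.frame(site = 1000L, alt = "T", alt_reads = 1L)
  par2 <- data.frame(site = 1000L, alt = "T", alt_reads = 2L)
  expect_equal(nrow(filter_snvs(make_variant(40L, 20L), pol, par1)$kept), 1L)
  expect_equal(nrow(filter_snvs(make_variant(40L, 20L), pol, par2)$kept), 0L)
})

test_that("INDEL thresholds match the published filter chain", {
  pol <- filter_policy()
  expect_equal(nrow(filter_indels(make_variant(30L, 9L), pol)$kept), 0L)  # count < 10
  expect_equal(nrow(filter_indels(make_variant(30L, 10L), pol)$kept), 1L) # VAF 0.333
  expect_equal(nrow(filter_indels(make_variant(19L, 10L), pol)$kept), 0L) # coverage
  expect_equal(nrow(filter_indels(make_variant(40L, 29L), pol)$kept), 0L) # 0.725
  expect_equal(nrow(filter_indels(make_variant(40L, 28L), pol)$kept), 1L) # 0.70
  # hemizygous VAF 0.69 removed, 0.70 kept
  expect_equal(nrow(filter_indels(make_variant(100L, 69L, "hemizygous"), pol)$kept), 0L)
  expect_equal(nrow(filter_indels(make_variant(100L, 70L, "hemizygous"), pol)$kept), 1L)
})

test_that("filter chains agree with independent predicates on random tables", {
  set.seed(301)
  pol <- filter_policy(
    known_sites = paste0(sample.int(1e6, 200), ":T"),
    sister_clones = list(data.frame(site = sample.int(1e6, 300),
                                    alt = "T", depth = 30L))
  )
  for (rep in 1:3) {
    v <- random_variant_table(500)
    parental <- data.frame(site = v$site[1:50], alt = v$alt[1:50],
                           alt_reads = sample(0:4, 50, replace = TRUE))
    par_alt <- rep(0, 500)
    m <- match(paste0(v$site, ":", v$alt),
               paste0(parental$site, ":", parental$alt))
    par_alt[!is.na(m)] <- parental$alt_reads[m[!is.na(m)]]
    known <- paste0(v$site, ":", v$alt) %in% pol$known_sites
    sis_keys <- with(pol$sister_clones[[1]],
                     paste0(site, ":", alt)[depth >= pol$min_depth])
    sister <- paste0(v$site, ":", v$alt) %in% sis_keys

    res <- filter_snvs(v, pol, parental)
    expect_identical(sort(res$kept$site),
                     sort(v$site[oracle_snv_keep(v, pol, par_alt, known, sister)]))

    sis_keys_i <- with(pol$sister_clones[[1]],
                       paste0(site, ":", alt)[depth >= pol$indel_min_depth])
    sister_i <- paste0(v$site, ":", v$alt) %in% sis_keys_i
    res_i <- filter_indels(v, pol, parental)
    expect_identical(sort(res_i$kept$site),
                     sort(v$site[oracle_indel_keep(v, pol, par_alt, known, sister_i)]))
  }
})

test_that("filtering is idempotent and the trace covers every stage", {
  set.seed(302)
  v <- random_variant_table(200)
  pol <- filter_policy()
  first <- filter_snvs(v, pol)
  second <- filter_snvs(first$kept, pol)
  expect_identical(as.data.frame(first$kept), as.data.frame(second$kept))
  expect_identical(
    names(first$trace),
    c("site", "alt", "depth", "parental_sharing", "known_sites",
      "sister_sharing", "repeat_flank", "vaf_window", "verdict")
  )
  expect_identical(
    first$trace$verdict == "pass",
    unname(apply(first$trace[, 3:8], 1, all))
  )
})

test_that("incomplete variants get an error verdict, not a silent drop", {
  v <- make_variant(c(40L, NA), c(20L, 20L), site = c(1L, 2L))
  res <- filter_snvs(v, filter_policy())
  expect_identical(res$trace$verdict, c("pass", "error"))
  expect_equal(nrow(res$kept), 1L)
  expect_error(filter_snvs(data.frame(site = 1), filter_policy()),
               "missing required columns")
})

test_that("the 35% bound removes low-VAF SNVs at the exact binomial rate", {
  # a mutation from generation 1 has true VAF 0.25; at ~40x conventional
  # WGS the chance its sampled VAF reaches the 35-65% window is the
  # binomial tail, mixed over the Poisson depth - this is why shallow WGS
  # misses most non-clonal SNVs
  t_range <- 0:150
  p_keep_given_t <- vapply(t_range, function(t) {
    if (t < 20L) return(0)
    lo <- ceiling(0.35 * t); hi <- floor(0.65 * t)
    if (lo > hi) return(0)
    sum(stats::dbinom(lo:hi, t, 0.25))
  }, numeric(1))
  p_keep <- sum(stats::dpois(t_range, 40) * p_keep_given_t)

  set.seed(303)
  n <- 4000
  depth <- stats::rpois(n, 40)
  alt <- stats::rbinom(n, depth, 0.25)
  v <- data.frame(site = seq_len(n), ref = "C", alt = "T",
                  depth = depth, alt_count = alt, chrom_class = "autosome")
  kept <- nrow(filter_snvs(v, filter_policy())$kept)
  se <- sqrt(p_keep * (1 - p_keep) / n)
  expect_lt(abs(kept / n - p_keep), 4 * se + 1e-9)
  # and a clonal 50% SNV is kept most of the time
  alt50 <- stats::rbinom(n, depth, 0.5)
  v50 <- v; v50$alt_count <- alt50
  expect_gt(nrow(filter_snvs(v50, filter_policy())$kept) / n, 0.8)
})

test_that("repeat flanks are recognised from sequence", {
  expect_true(repeat_flank_flag("ACGTAAAAACG"))   # homopolymer run of 5
  expect_true(repeat_flank_flag("TTACACACGTA"))   # 3 copies of AC
  expect_false(repeat_flank_flag("ACGTACGTACG"))
  expect_identical(repeat_flank_flag(c("AAAAA", "ACGTA")), c(TRUE, FALSE))
})
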