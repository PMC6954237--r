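# Shared fixtures and independent oracles used across test files.

small_config <- function(...) {
  args <- list(...)
  defaults <- list(
    genome_length = 1e5, generations = 6, burst_window = c(1, 3),
    mu_burst = 2, mu_background = 0.2, n_preexisting = 10,
    sex_chromosome_fraction = 0, seed = NULL
  )
  do.call(sim_config, utils::modifyList(defaults, args))
}

# Independent single-expression filter predicates (coded separately from
# the filter chain; keep these as plain boolean algebra on the columns).
oracle_snv_keep <- function(v, policy, parental_alt, known, sister) {
  vaf <- v$alt_count / v$depth
  v$depth >= policy$min_depth &
    parental_alt <= policy$parental_max_alt &
    !known & !sister &
    !(if (is.null(v$repeat_flag)) rep(FALSE, nrow(v)) else v$repeat_flag) &
    ifelse(v$chrom_class == "hemizygous",
           vaf >= policy$snv_hemizygous_min,
           vaf >= policy$snv_vaf_window[1] & vaf <= policy$snv_vaf_window[2])
}

oracle_indel_keep <- function(v, policy, parental_alt, known, sister) {
  vaf <- v$alt_count / v$depth
  v$depth >= policy$indel_min_depth &
    v$alt_count >= policy$indel_min_count &
    parental_alt <= policy$parental_max_alt &
    !known & !sister &
    !(if (is.null(v$repeat_flag)) rep(FALSE, nrow(v)) else v$repeat_flag) &
    ifelse(v$chrom_class == "hemizygous",
           vaf >= policy$indel_hemizygous_min,
           vaf >= policy$indel_vaf_window[1] & vaf <= policy$indel_vaf_window[2])
}

random_variant_table <- function(n) {
  data.frame(
    site = sample.int(1e6, n),
    ref = sample(c("A", "C", "G", "T"), n, replace = TRUE),
    alt = sample(c("A", "C", "G", "T"), n, replace = TRUE),
    depth = sample(5:60, n, replace = TRUE),
    alt_count = NA_integer_,
    chrom_class = sample(c("autosome", "hemizygous"), n, replace = TRUE,
                         prob = c(0.9, 0.1)),
    repeat_flag = stats::runif(n) < 0.1,
    stringsAsFactors = FALSE
  ) -> v
  v$alt_count <- vapply(v$depth, function(d) sample.int(d + 1L, 1L) - 1L,
                        integer(1))
  v$alt <- ifelse(v$alt == v$ref, "T", v$alt)
  v$alt[v$alt == v$ref] <- "G"
  v
}

# draw n SNV rows (ref/alt/context) from a signature profile
draw_snvs_from_signature <- function(n, sig) {
  labs <- class96_labels()
  lab <- sample(labs, n, replace = TRUE, prob = as.numeric(sig))
  data.frame(
    ref = substr(lab, 3, 3), alt = substr(lab, 5, 5),
    context = paste0(substr(lab, 1, 1), substr(lab, 3, 3), substr(lab, 7, 7)),
    stringsAsFactors = FALSE
  )
}
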