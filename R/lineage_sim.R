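#' Configuration for a clonal-expansion simulation
#'
#' Describes a clone grown from a single founder cell through \code{G}
#' synchronous binary divisions (final population \code{2^G} cells) on a
#' virtual contig. Mutation pressure is Poisson per cell division:
#' \code{mu_background} everywhere except inside \code{burst_window}, an
#' inclusive generation interval during which the rate is \code{mu_burst}.
#' The window models the transient hypermutation phase at the onset of
#' reprogramming, when the G1/S checkpoint is attenuated for a small number
#' of early divisions.
#'
#' Defaults describe one reprogrammed clone as characterised by deep
#' subline sequencing: ~300 expected burst mutations drawn from a
#' Signature-17-like transversion profile confined to generations 1--4,
#' a low continuous transition-biased background, ~40x WGS coverage,
#' ~1e5-read amplicon redundancy, and a 0.1% VAF detection floor.
#'
#' @param genome_length Virtual contig length in bp.
#' @param generations Number of divisions G; founder is generation 0.
#' @param burst_window Inclusive generation interval \code{c(k1, k2)} of
#'   elevated rate.
#' @param mu_background Expected mutations per cell division outside the
#'   window (Poisson mean).
#' @param mu_burst Expected mutations per division inside the window.
#' @param n_preexisting Heterozygous variants already present in the
#'   founder (generation 0).
#' @param burst_signature,background_signature \code{signature_profile}s
#'   from which mutation classes are drawn.
#' @param wgs_depth Mean WGS coverage per site.
#' @param amplicon_reads Mean amplicon reads per site.
#' @param seq_error Per-base miscall probability, spread uniformly over the
#'   three non-reference bases.
#' @param vaf_floor Amplicon detection floor as a VAF (default 0.001, the
#'   0.1% level below which signal cannot be distinguished from background).
#' @param sex_chromosome_fraction Fraction of sites flagged hemizygous.
#' @param seed RNG seed, or NULL to use the current RNG state.
#' @return A \code{sim_config} list.
#' @export
sim_config <- function(genome_length = 1e6,
                       generations = 13,
                       burst_window = c(1, 4),
                       mu_background = 0.1,
                       mu_burst = 10,
                       n_preexisting = 50,
                       burst_signature = sig17_like(),
                       background_signature = background_transition_signature(),
                       wgs_depth = 40,
                       amplicon_reads = 1e5,
                       seq_error = 3e-4,
                       vaf_floor = 0.001,
                       sex_chromosome_fraction = 0,
                       seed = NULL) {
  cfg <- list(
    genome_length = as.numeric(genome_length),
    generations = as.integer(generations),
    burst_window = as.integer(burst_window),
    mu_background = mu_background,
    mu_burst = mu_burst,
    n_preexisting = as.integer(n_preexisting),
    burst_signature = burst_signature,
    background_signature = background_signature,
    wgs_depth = wgs_depth,
    amplicon_reads = amplicon_reads,
    seq_error = seq_error,
    vaf_floor = vaf_floor,
    sex_chromosome_fraction = sex_chromosome_fraction,
    seed = seed
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (generations < 1L) stop("generations must be >= 1")
    if (length(burst_window) != 2L ||
        burst_window[1] < 0L || burst_window[1] > burst_window[2] ||
        burst_window[2] > generations) {
      stop("burst_window must satisfy 0 <= k1 <= k2 <= generations")
    }
    if (mu_background < 0 || mu_burst < mu_background) {
      stop("rates must satisfy mu_burst >= mu_background >= 0")
    }
    if (n_preexisting < 0L) stop("n_preexisting must be >= 0")
    for (sig in list(burst_signature, background_signature)) {
      if (abs(sum(sig) - 1) > 1e-9 || any(sig < 0)) {
        stop("signature weights must be non-negative and sum to 1")
      }
    }
    if (vaf_floor <= 0 || vaf_floor >= 0.5) stop("vaf_floor must be in (0, 0.5)")
    if (seq_error < 0 || seq_error > 0.75) stop("seq_error out of range")
    if (sex_chromosome_fraction < 0 || sex_chromosome_fraction > 1) {
      stop("sex_chromosome_fraction must be in [0, 1]")
    }
  })
  invisible(cfg)
}

#' Expected total mutation count under a configuration
#'
#' Closed form: \code{n_preexisting + sum_k 2^k * mu_k} with \code{mu_k}
#' equal to the burst rate inside the window and the background rate
#' outside.
#'
#' @param cfg A \code{sim_config}.
#' @param burst_only Count only window generations.
#' @return Expected number of mutations.
#' @export
expected_mutation_count <- function(cfg, burst_only = FALSE) {
  k <- seq_len(cfg$generations)
  in_burst <- k >= cfg$burst_window[1] & k <= cfg$burst_window[2] &
    cfg$burst_window[1] >= 1L
  mu <- ifelse(in_burst, cfg$mu_burst, cfg$mu_background)
  if (burst_only) sum(2^k[in_burst] * cfg$mu_burst)
  else cfg$n_preexisting + sum(2^k * mu)
}

draw_mutation_classes <- function(n, sig) {
  labs <- class96_labels()
  idx <- sample.int(96L, n, replace = TRUE, prob = as.numeric(sig))
  lab <- labs[idx]
  ref <- substr(lab, 3, 3)
  alt <- substr(lab, 5, 5)
  ctx <- paste0(substr(lab, 1, 1), ref, substr(lab, 7, 7))
  # emit either strand with equal probability, as a caller would observe
  flip <- sample(c(TRUE, FALSE), n, replace = TRUE)
  ref[flip] <- chartr("ACGT", "TGCA", ref[flip])
  alt[flip] <- chartr("ACGT", "TGCA", alt[flip])
  ctx[flip] <- revcomp(ctx[flip])
  data.frame(ref = ref, alt = alt, context = ctx, class96 = lab,
             stringsAsFactors = FALSE)
}

#' Simulate a clonal expansion with a transient hypermutation window
#'
#' Grows a complete binary division tree for \code{generations} divisions.
#' For each generation k the number of new mutations is
#' Poisson(\code{2^k * mu_k}); each mutation is attached to a uniformly
#' chosen cell (lineage index in \code{[0, 2^k)}) and is inherited by that
#' cell's whole subtree, so a mutation from generation k is carried by a
#' fraction \code{2^-k} of final cells and has true heterozygous VAF
#' \code{2^-(k+1)}. Mutation classes are drawn from the burst signature
#' inside the window and the background signature outside; sites are drawn
#' without replacement from the virtual contig (infinite-sites).
#'
#' @param config A \code{sim_config}.
#' @return A \code{lineage_mutation_set}: data frame with columns
#'   \code{id}, \code{site}, \code{ref}, \code{alt}, \code{context},
#'   \code{class96}, \code{generation}, \code{lineage_index},
#'   \code{is_burst}, \code{zygosity}; the configuration is kept in the
#'   \code{config} attribute.
#' @export
#' @examples
#' cfg <- sim_config(generations = 6, mu_burst = 2, mu_background = 0.1,
#'                   n_preexisting = 10, seed = 1)
#' mset <- simulate_clone(cfg)
#' table(mset$generation)
simulate_clone <- function(config) {
  validate_sim_config(config)
  if (expected_mutation_count(config) > config$genome_length) {
    stop("expected mutation count exceeds genome_length; infinite-sites model violated")
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  G <- config$generations
  gens <- integer(0); lineage <- numeric(0); burst <- logical(0)
  if (config$n_preexisting > 0L) {
    gens <- rep(0L, config$n_preexisting)
    lineage <- rep(0, config$n_preexisting)
    burst <- rep(FALSE, config$n_preexisting)
  }
  for (k in seq_len(G)) {
    in_burst <- k >= config$burst_window[1] && k <= config$burst_window[2]
    mu <- if (in_burst) config$mu_burst else config$mu_background
    n_k <- stats::rpois(1L, 2^k * mu)
    if (n_k > 0L) {
      gens <- c(gens, rep(k, n_k))
      # uniform cell choice among the 2^k cells alive at generation k
      lineage <- c(lineage, floor(stats::runif(n_k) * 2^k))
      burst <- c(burst, rep(in_burst, n_k))
    }
  }
  n <- length(gens)
  cls <- if (n > 0L) {
    rbind(
      draw_mutation_classes(sum(!burst), config$background_signature),
      draw_mutation_classes(sum(burst), config$burst_signature)
    )[order(c(which(!burst), which(burst))), , drop = FALSE]
  } else {
    data.frame(ref = character(0), alt = character(0),
               context = character(0), class96 = character(0))
  }
  sites <- if (n > 0L) sample.int(config$genome_length, n) else integer(0)
  zyg <- if (config$sex_chromosome_fraction > 0 && n > 0L) {
    ifelse(stats::runif(n) < config$sex_chromosome_fraction,
           "hemizygous", "heterozygous")
  } else rep("heterozygous", n)
  mset <- data.frame(
    id = if (n > 0L) sprintf("m%05d", seq_len(n)) else character(0),
    site = sites,
    ref = cls$ref, alt = cls$alt, context = cls$context, class96 = cls$class96,
    generation = gens,
    lineage_index = lineage,
    is_burst = burst,
    zygosity = zyg,
    stringsAsFactors = FALSE
  )
  structure(mset, config = config,
            class = c("lineage_mutation_set", "data.frame"))
}

#' True VAF of a lineage mutation in the final clone
#'
#' A mutation acquired at generation k is carried by a fraction
#' \code{2^-k} of cells. On an autosome it sits on one of two alleles, so
#' its true VAF is \code{2^-(k+1)}: a founder (k = 0) heterozygous variant
#' is at exactly 50%, one allele of every cell in the colony. On a
#' hemizygous (male sex chromosome) site there is a single allele and the
#' VAF equals the carrier fraction \code{2^-k}.
#'
#' @param generation Integer vector of origin generations (k >= 0).
#' @param zygosity \code{"heterozygous"} or \code{"hemizygous"} (recycled).
#' @return Numeric vector of true VAFs.
#' @export
#' @examples
#' true_vaf(0)                       # 0.5
#' true_vaf(0, "hemizygous")         # 1
#' true_vaf(3)                       # 0.0625
true_vaf <- function(generation, zygosity = "heterozygous") {
  stopifnot(all(generation >= 0))
  zyg <- rep_len(zygosity, length(generation))
  ifelse(zyg == "hemizygous", 2^(-generation), 2^(-(generation + 1)))
}

#' True VAFs of every mutation in a set
#' @param mset A \code{lineage_mutation_set}.
#' @return Numeric vector aligned with the rows of \code{mset}.
#' @export
true_vafs <- function(mset) true_vaf(mset$generation, mset$zygosity)

#' Simulate read counts over the mutated sites
#'
#' Emits one observation per site: total reads Poisson around the assay
#' depth and alt reads Binomial with success probability
#' \code{v*(1-e) + (1-v)*e/3}, where v is the sample's true VAF at the
#' site and e the per-base miscall rate (miscalls spread uniformly over
#' the three non-reference bases). Supported samples: \code{"parent"}
#' (true clone VAFs), a subline set (every founder mutation at 50%), and
#' \code{"parental_somatic"} (only pre-existing, generation-0, variants
#' present).
#'
#' @param mset A \code{lineage_mutation_set} (parent clone or subline).
#' @param config A \code{sim_config} (depths and error rate).
#' @param assay \code{"wgs"} or \code{"amplicon"}.
#' @param sample \code{"parent"}, \code{"subline"} or
#'   \code{"parental_somatic"}.
#' @param extra_null_sites Number of additional unmutated sites to emit as
#'   error-only background observations (true VAF 0).
#' @return Data frame with columns \code{site}, \code{id},
#'   \code{total_reads}, \code{alt_reads}, \code{assay}, \code{sample},
#'   \code{true_vaf}.
#' @export
sample_reads <- function(mset, config, assay = c("wgs", "amplicon"),
                         sample = c("parent", "subline", "parental_somatic"),
                         extra_null_sites = 0L) {
  assay <- match.arg(assay)
  sample <- match.arg(sample)
  depth <- switch(assay, wgs = config$wgs_depth, amplicon = config$amplicon_reads)
  v <- switch(sample,
    parent = true_vafs(mset),
    subline = true_vafs(mset),
    parental_somatic = ifelse(mset$generation == 0L,
                              true_vaf(0, mset$zygosity), 0)
  )
  site <- mset$site
  id <- mset$id
  if (extra_null_sites > 0L) {
    null_sites <- setdiff(
      sample.int(config$genome_length, extra_null_sites + nrow(mset)),
      mset$site
    )[seq_len(extra_null_sites)]
    site <- c(site, null_sites)
    id <- c(id, sprintf("null%05d", seq_len(extra_null_sites)))
    v <- c(v, rep(0, extra_null_sites))
  }
  n <- length(site)
  total <- stats::rpois(n, depth)
  e <- config$seq_error
  p <- v * (1 - e) + (1 - v) * e / 3
  alt <- stats::rbinom(n, total, p)
  data.frame(
    site = site, id = id, total_reads = total, alt_reads = alt,
    assay = assay, sample = sample, true_vaf = v,
    stringsAsFactors = FALSE
  )
}

#' Mutations carried by one final cell of the clone
#'
#' Index arithmetic on the complete binary tree: the ancestor of final
#' cell \code{leaf_index} at generation k is \code{leaf_index \%/\%
#' 2^(G-k)}, so a mutation (k, i) is carried iff that quotient equals i.
#'
#' @param mset A \code{lineage_mutation_set}.
#' @param leaf_index Cell index in \code{[0, 2^G)}.
#' @return Logical vector over the rows of \code{mset}.
#' @export
leaf_carries <- function(mset, leaf_index) {
  G <- attr(mset, "config")$generations
  if (leaf_index < 0 || leaf_index >= 2^G) {
    stop("leaf_index out of range [0, 2^G)")
  }
  floor(leaf_index / 2^(G - mset$generation)) == mset$lineage_index
}

#' Expand a single cell of the clone into a subline
#'
#' Picks final cell \code{leaf_index}, which founds a subline carrying
#' exactly the parent-clone mutations present in that cell — all at
#' subline VAF 50% (or 100% hemizygous), since the subline is clonal for
#' them. The subline then grows for \code{subline_generations} divisions
#' (default 14, matching a ~2-week single-cell expansion) accruing its own
#' background mutations at the background rate.
#'
#' @param mset Parent \code{lineage_mutation_set}.
#' @param config The parent \code{sim_config}.
#' @param leaf_index Founding cell index in \code{[0, 2^G)}.
#' @param subline_generations Divisions of subline growth.
#' @return A \code{lineage_mutation_set} for the subline; inherited
#'   mutations have \code{generation = 0} in the subline frame and keep
#'   their parent identity in columns \code{parent_id} and
#'   \code{parent_generation} (\code{NA} for subline-private mutations).
#' @export
derive_subline <- function(mset, config, leaf_index, subline_generations = 14L) {
  carried <- leaf_carries(mset, leaf_index)
  inherited <- as.data.frame(mset)[carried, , drop = FALSE]
  sub_cfg <- config
  sub_cfg$generations <- as.integer(subline_generations)
  sub_cfg$burst_window <- c(0L, 0L)        # no hypermutation during expansion
  sub_cfg$mu_burst <- sub_cfg$mu_background
  sub_cfg$n_preexisting <- 0L
  sub_cfg$seed <- NULL
  private <- simulate_clone(sub_cfg)
  # resample private sites colliding with inherited ones (infinite sites)
  while (any(private$site %in% inherited$site)) {
    clash <- private$site %in% inherited$site
    private$site[clash] <- sample.int(config$genome_length, sum(clash))
  }
  out <- data.frame(
    id = c(paste0("p_", inherited$id),
           if (nrow(private) > 0L) paste0("s_", private$id) else character(0)),
    site = c(inherited$site, private$site),
    ref = c(inherited$ref, private$ref),
    alt = c(inherited$alt, private$alt),
    context = c(inherited$context, private$context),
    class96 = c(inherited$class96, private$class96),
    generation = c(rep(0L, nrow(inherited)), private$generation),
    lineage_index = c(rep(0, nrow(inherited)), private$lineage_index),
    is_burst = c(inherited$is_burst, private$is_burst),
    zygosity = c(inherited$zygosity, private$zygosity),
    parent_id = c(inherited$id, rep(NA_character_, nrow(private))),
    parent_generation = c(inherited$generation,
                          rep(NA_integer_, nrow(private))),
    stringsAsFactors = FALSE
  )
  structure(out, config = sub_cfg, leaf_index = leaf_index,
            class = c("lineage_mutation_set", "data.frame"))
}

#' Explicit-tree oracle: mutations carried by every final cell
#'
#' Recursively walks the explicit division tree, passing each cell's
#' mutation set to its two children and adding the mutations assigned to
#' the child cells, down to the final generation. Only practical for
#' \code{G <= 12}; used to cross-check the index-arithmetic
#' representation.
#'
#' @param mset A \code{lineage_mutation_set}.
#' @return List of integer row-index vectors, one per final cell in leaf
#'   order (leaf 0 first).
#' @export
enumerate_leaf_mutations <- function(mset) {
  G <- attr(mset, "config")$generations
  if (G > 12L) stop("explicit enumeration supported only for G <= 12")
  by_gen <- split(seq_len(nrow(mset)), mset$generation)
  descend <- function(k, i, acc) {
    rows <- by_gen[[as.character(k)]]
    if (!is.null(rows)) {
      acc <- c(acc, rows[mset$lineage_index[rows] == i])
    }
    if (k == G) return(list(acc))
    c(descend(k + 1L, 2 * i, acc), descend(k + 1L, 2 * i + 1, acc))
  }
  descend(0L, 0, integer(0))
}

#' @export
print.lineage_mutation_set <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf(
    "<lineage_mutation_set> %d mutations, G = %d, burst window [%d, %d]\n",
    nrow(x), cfg$generations, cfg$burst_window[1], cfg$burst_window[2]
  ))
  cat(sprintf("  pre-existing: %d, burst: %d, background: %d\n",
              sum(x$generation == 0L), sum(x$is_burst),
              sum(!x$is_burst & x$generation > 0L)))
  invisible(x)
}
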