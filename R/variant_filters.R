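#' Post-call filter policy for SNVs and INDELs
#'
#' Encodes the thresholds applied to caller output before a variant is
#' counted: a minimum depth of 20; an autosomal VAF window of 35--65% for
#' SNVs (a heterozygous variant present in every cell of the clone sits
#' near 50%) with hemizygous sites on the male sex chromosome required at
#' VAF >= 75%; exclusion of candidates shared with the parental somatic
#' cells (parental alt reads >= 2), of known germline sites, of calls
#' shared among sister clones from the same experiment, and of calls with
#' homopolymeric or simple-repeat flanks. INDELs use coverage >= 20, a
#' minimum alt count of 10, a 30--70% autosomal window and a hemizygous
#' minimum of 70%.
#'
#' @param min_depth Minimum read depth for SNVs.
#' @param snv_vaf_window Autosomal SNV VAF window (inclusive).
#' @param snv_hemizygous_min Minimum VAF on hemizygous sites (SNV).
#' @param indel_min_depth,indel_min_count,indel_vaf_window,indel_hemizygous_min
#'   INDEL thresholds.
#' @param parental_max_alt Maximum parental alt reads tolerated; a variant
#'   with parental alt reads strictly greater than this is treated as
#'   shared with the parental cells (default 1, i.e. excluded at >= 2).
#' @param known_sites Character vector of \code{"site:alt"} keys treated as
#'   known germline variants (dbSNP analogue).
#' @param sister_clones List of sister-clone call tables (data frames with
#'   \code{site}, \code{alt}, \code{depth}).
#' @return A \code{filter_policy} list.
#' @export
filter_policy <- function(min_depth = 20L,
                          snv_vaf_window = c(0.35, 0.65),
                          snv_hemizygous_min = 0.75,
                          indel_min_depth = 20L,
                          indel_min_count = 10L,
                          indel_vaf_window = c(0.30, 0.70),
                          indel_hemizygous_min = 0.70,
                          parental_max_alt = 1L,
                          known_sites = character(0),
                          sister_clones = list()) {
  stopifnot(
    min_depth >= 0, indel_min_depth >= 0, indel_min_count >= 0,
    all(snv_vaf_window >= 0 & snv_vaf_window <= 1),
    all(indel_vaf_window >= 0 & indel_vaf_window <= 1),
    snv_vaf_window[1] <= snv_vaf_window[2],
    indel_vaf_window[1] <= indel_vaf_window[2]
  )
  structure(
    list(min_depth = min_depth, snv_vaf_window = snv_vaf_window,
         snv_hemizygous_min = snv_hemizygous_min,
         indel_min_depth = indel_min_depth,
         indel_min_count = indel_min_count,
         indel_vaf_window = indel_vaf_window,
         indel_hemizygous_min = indel_hemizygous_min,
         parental_max_alt = parental_max_alt,
         known_sites = known_sites,
         sister_clones = sister_clones),
    class = "filter_policy"
  )
}

site_alt_key <- function(site, alt) paste0(site, ":", alt)

REQUIRED_VARIANT_FIELDS <- c("site", "ref", "alt", "depth", "alt_count",
                             "chrom_class")

filter_chain <- function(variants, policy, parental_obs,
                         min_depth, min_count, vaf_window, hemi_min) {
  n <- nrow(variants)
  missing_fields <- setdiff(REQUIRED_VARIANT_FIELDS, names(variants))
  if (length(missing_fields) > 0L) {
    stop("variant table is missing required columns: ",
         paste(missing_fields, collapse = ", "))
  }
  repeat_flag <- if (!is.null(variants$repeat_flag)) variants$repeat_flag
                 else rep(FALSE, n)

  # per-variant field completeness: an NA in a required field yields an
  # error verdict for that variant, never a silent drop
  row_ok <- stats::complete.cases(
    variants[, REQUIRED_VARIANT_FIELDS, drop = FALSE]
  )

  parental_alt <- rep(0, n)
  if (!is.null(parental_obs) && nrow(parental_obs) > 0L) {
    m <- match(site_alt_key(variants$site, variants$alt),
               site_alt_key(parental_obs$site, parental_obs$alt))
    parental_alt[!is.na(m)] <- parental_obs$alt_reads[m[!is.na(m)]]
  }

  sister_keys <- character(0)
  for (sis in policy$sister_clones) {
    ok <- sis$depth >= min_depth
    sister_keys <- c(sister_keys, site_alt_key(sis$site[ok], sis$alt[ok]))
  }

  vaf <- variants$alt_count / variants$depth
  hemi <- variants$chrom_class == "hemizygous"

  stages <- list(
    depth = variants$depth >= min_depth & variants$alt_count >= min_count,
    parental_sharing = parental_alt <= policy$parental_max_alt,
    known_sites = !(site_alt_key(variants$site, variants$alt) %in%
                      policy$known_sites),
    sister_sharing = !(site_alt_key(variants$site, variants$alt) %in%
                         sister_keys),
    repeat_flank = !repeat_flag,
    vaf_window = ifelse(hemi, vaf >= hemi_min,
                        vaf >= vaf_window[1] & vaf <= vaf_window[2])
  )
  trace <- as.data.frame(stages)
  trace[] <- lapply(trace, function(x) ifelse(row_ok, x, NA))
  verdict <- ifelse(row_ok,
                    Reduce(`&`, stages),
                    NA)
  trace$verdict <- ifelse(is.na(verdict), "error",
                          ifelse(verdict, "pass", "fail"))
  trace <- cbind(
    data.frame(site = variants$site, alt = variants$alt,
               stringsAsFactors = FALSE),
    trace
  )
  list(kept = variants[!is.na(verdict) & verdict, , drop = FALSE],
       trace = trace)
}

#' Filter SNV candidates with the post-call exclusion chain
#'
#' Applies, in trace order: depth, parental sharing, known germline sites,
#' sister-clone sharing, repeat flanks, and the VAF window. The stages are
#' conjunctive, so the kept set does not depend on their order; the trace
#' records every stage decision for every variant.
#'
#' @param variants Data frame with columns \code{site}, \code{ref},
#'   \code{alt}, \code{depth}, \code{alt_count}, \code{chrom_class}
#'   (\code{"autosome"} or \code{"hemizygous"}), optional
#'   \code{repeat_flag}.
#' @param policy A \code{filter_policy}.
#' @param parental_obs Parental-cell read counts: data frame with
#'   \code{site}, \code{alt}, \code{alt_reads} (or NULL).
#' @return List with \code{kept} (the passing subset of \code{variants})
#'   and \code{trace} (per-variant stage decisions and final verdict:
#'   pass / fail / error).
#' @export
#' @examples
#' pol <- filter_policy()
#' v <- data.frame(site = 1:2, ref = "C", alt = "T",
#'                 depth = c(19L, 40L), alt_count = c(10L, 20L),
#'                 chrom_class = "autosome")
#' filter_snvs(v, pol, NULL)$trace$verdict   # "fail" (depth), "pass"
filter_snvs <- function(variants, policy = filter_policy(),
                        parental_obs = NULL) {
  filter_chain(variants, policy, parental_obs,
               min_depth = policy$min_depth, min_count = 0L,
               vaf_window = policy$snv_vaf_window,
               hemi_min = policy$snv_hemizygous_min)
}

#' Filter INDEL candidates
#'
#' As \code{\link{filter_snvs}} but with the INDEL thresholds: coverage
#' >= 20, minimum alt count 10, VAF 30--70% autosomal, hemizygous minimum
#' 70%, with the known-site list playing the dbSNP-common role.
#'
#' @inheritParams filter_snvs
#' @return As \code{\link{filter_snvs}}.
#' @export
filter_indels <- function(variants, policy = filter_policy(),
                          parental_obs = NULL) {
  filter_chain(variants, policy, parental_obs,
               min_depth = policy$indel_min_depth,
               min_count = policy$indel_min_count,
               vaf_window = policy$indel_vaf_window,
               hemi_min = policy$indel_hemizygous_min)
}

#' Flag repeat-context sites from flanking sequence
#'
#' Operational repeat definition used when sequence is available: a
#' homopolymer run of length >= 5, or >= 3 tandem copies of a mono- or
#' di-nucleotide unit, anywhere within +/- 5 bp of the site.
#'
#' @param flank Character vector of 11-mers centred on each site (or
#'   longer; the centre is taken as the site).
#' @return Logical vector.
#' @export
repeat_flank_flag <- function(flank) {
  vapply(toupper(flank), function(s) {
    grepl("A{5}|C{5}|G{5}|T{5}", s) || grepl("(..)\\1\\1", s)
  }, logical(1), USE.NAMES = FALSE)
}
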