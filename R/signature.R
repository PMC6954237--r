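BASES <- c("A", "C", "G", "T")
SUBSTITUTIONS <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
TRANSITION_CLASSES <- c("C>T", "T>C")

#' Canonical labels of the 96 substitution-in-context classes
#'
#' Labels follow the COSMIC convention \code{"5'[ref>alt]3'"} with the
#' substitution expressed on the pyrimidine strand, ordered by substitution
#' type (C>A, C>G, C>T, T>A, T>C, T>G), then 5' base, then 3' base.
#'
#' @return Character vector of length 96.
#' @export
#' @examples
#' head(class96_labels())
class96_labels <- function() {
  unlist(lapply(SUBSTITUTIONS, function(s) {
    ref <- substr(s, 1, 1)
    as.vector(t(outer(BASES, BASES, function(p5, p3) {
      paste0(p5, "[", s, "]", p3)
    })))
  }))
}

revcomp <- function(x) {
  chartr("ACGT", "TGCA", vapply(strsplit(x, NULL), function(b) {
    paste(rev(b), collapse = "")
  }, character(1)))
}

#' Map a substitution with trinucleotide context to its 96-class label
#'
#' Substitutions whose reference base is a purine (A or G) are mapped to the
#' reverse-complement strand so every substitution is expressed
#' pyrimidine-centred; the 192 raw (ref, alt, context) cases therefore
#' collapse onto 96 classes, each hit exactly twice.
#'
#' @param ref,alt Single reference/alternate bases (vectors recycled
#'   elementwise).
#' @param context 3-mer centred on the mutated base; its middle base must
#'   equal \code{ref}.
#' @param as_index Return the integer class index (1..96, in
#'   \code{class96_labels()} order) instead of the label.
#' @return Character labels or integer indices, same length as the inputs.
#' @export
#' @examples
#' classify_96("T", "G", "CTT")   # "C[T>G]T"
#' classify_96("A", "C", "AAG")   # same class, via reverse complement
classify_96 <- function(ref, alt, context, as_index = FALSE) {
  n <- max(length(ref), length(alt), length(context))
  ref <- toupper(rep_len(ref, n))
  alt <- toupper(rep_len(alt, n))
  context <- toupper(rep_len(context, n))
  if (any(!ref %in% BASES) || any(!alt %in% BASES)) {
    stop("ref and alt must be single bases in {A, C, G, T}")
  }
  if (any(nchar(context) != 3L)) stop("context must be a 3-mer")
  if (any(grepl("[^ACGT]", context))) stop("context contains non-ACGT characters")
  if (any(substr(context, 2, 2) != ref)) {
    stop("middle base of context must equal ref")
  }
  if (any(ref == alt)) stop("ref and alt must differ")
  flip <- ref %in% c("A", "G")
  if (any(flip)) {
    ref[flip] <- chartr("ACGT", "TGCA", ref[flip])
    alt[flip] <- chartr("ACGT", "TGCA", alt[flip])
    context[flip] <- revcomp(context[flip])
  }
  lab <- paste0(
    substr(context, 1, 1), "[", ref, ">", alt, "]", substr(context, 3, 3)
  )
  if (as_index) match(lab, class96_labels()) else lab
}

#' Construct a 96-class signature profile
#'
#' @param weights Non-negative numeric vector of length 96 (in
#'   \code{class96_labels()} order, or named by label). Normalised to sum 1.
#' @param label Character label for the signature.
#' @param n Optional number of observations the profile was computed from.
#' @return A \code{signature_profile}: named numeric vector of length 96
#'   summing to 1, with attributes \code{label} and \code{n}.
#' @export
signature_profile_new <- function(weights, label = "signature", n = NA_integer_) {
  labs <- class96_labels()
  if (!is.null(names(weights))) {
    if (!setequal(names(weights), labs)) {
      stop("named weights must cover exactly the 96 class labels")
    }
    weights <- weights[labs]
  }
  if (length(weights) != 96L) stop("weights must have length 96")
  if (any(weights < 0) || any(!is.finite(weights))) {
    stop("weights must be finite and non-negative")
  }
  s <- sum(weights)
  if (s <= 0) stop("weights must not all be zero")
  out <- as.numeric(weights) / s
  names(out) <- labs
  structure(out, class = "signature_profile", label = label, n = n)
}

#' @export
print.signature_profile <- function(x, ...) {
  cat("<signature_profile>", attr(x, "label"), "\n")
  top <- sort(unclass(x), decreasing = TRUE)[1:5]
  cat("  top classes:",
      paste(sprintf("%s=%.3f", names(top), top), collapse = ", "), "\n")
  if (!is.na(attr(x, "n"))) cat("  n =", attr(x, "n"), "\n")
  invisible(x)
}

#' Empirical 96-class profile of a set of SNVs
#'
#' @param snvs Data frame with columns \code{ref}, \code{alt},
#'   \code{context}.
#' @param label Label for the resulting profile.
#' @return A \code{signature_profile}; attribute \code{n} records the number
#'   of SNVs counted.
#' @export
signature_profile <- function(snvs, label = "empirical") {
  if (nrow(snvs) == 0L) stop("cannot profile an empty SNV set")
  idx <- classify_96(snvs$ref, snvs$alt, snvs$context, as_index = TRUE)
  counts <- tabulate(idx, nbins = 96L)
  signature_profile_new(counts, label = label, n = nrow(snvs))
}

#' Cosine similarity between two signature profiles
#'
#' @param p,q Numeric vectors of length 96 (signature profiles or raw
#'   non-negative weights).
#' @return Similarity in [0, 1] for non-negative inputs.
#' @export
cosine_similarity <- function(p, q) {
  p <- as.numeric(p); q <- as.numeric(q)
  if (length(p) != length(q)) stop("profiles must have equal length")
  np <- sqrt(sum(p^2)); nq <- sqrt(sum(q^2))
  if (np == 0 || nq == 0) stop("cannot compare a zero profile")
  sum(p * q) / (np * nq)
}

#' Transversion/transition summary of an SNV set
#'
#' Transitions are the C>T and T>C pyrimidine-strand classes; all other
#' substitutions are transversions. The ratio reported is tv/ts, the
#' convention used when summarising reprogramming-associated mutation loads.
#'
#' @param snvs Data frame with columns \code{ref}, \code{alt} (context not
#'   required).
#' @return List with \code{ts}, \code{tv} counts and \code{tv_ts_ratio}
#'   (\code{Inf} when there are no transitions).
#' @export
tstv <- function(snvs) {
  if (nrow(snvs) == 0L) {
    return(list(ts = 0L, tv = 0L, tv_ts_ratio = NA_real_))
  }
  ref <- toupper(snvs$ref); alt <- toupper(snvs$alt)
  pyr_ref <- ifelse(ref %in% c("A", "G"), chartr("ACGT", "TGCA", ref), ref)
  pyr_alt <- ifelse(ref %in% c("A", "G"), chartr("ACGT", "TGCA", alt), alt)
  sub <- paste0(pyr_ref, ">", pyr_alt)
  ts <- sum(sub %in% TRANSITION_CLASSES)
  tv <- length(sub) - ts
  list(ts = ts, tv = tv,
       tv_ts_ratio = if (ts == 0L) Inf else tv / ts)
}

#' Synthetic reference signatures
#'
#' Bundled synthetic stand-ins for catalogue signatures, built in code:
#' \code{sig17_like()} concentrates mass on T>G transversions at NTT
#' contexts (the hallmark of catalogue Signature 17), \code{sig18_like()}
#' on C>A transversions (the 8-oxoG-associated pattern), and
#' \code{background_transition_signature()} spreads mass over the C>T and
#' T>C transition classes typical of spontaneous culture mutagenesis.
#' The numeric weights are synthetic fixtures, not catalogue values.
#'
#' @param purity Fraction of mass on the characteristic classes; the
#'   remainder is spread uniformly over all 96 classes.
#' @return A \code{signature_profile}.
#' @export
sig17_like <- function(purity = 0.9) {
  labs <- class96_labels()
  w <- rep((1 - purity) / 96, 96)
  hot <- labs %in% paste0(BASES, "[T>G]T")
  w[hot] <- w[hot] + purity / sum(hot)
  signature_profile_new(w, label = "Sig17-like (synthetic)")
}

#' @rdname sig17_like
#' @export
sig18_like <- function(purity = 0.85) {
  labs <- class96_labels()
  w <- rep((1 - purity) / 96, 96)
  hot <- grepl("\\[C>A\\]", labs)
  w[hot] <- w[hot] + purity / sum(hot)
  signature_profile_new(w, label = "Sig18-like (synthetic)")
}

#' @rdname sig17_like
#' @export
background_transition_signature <- function(purity = 0.9) {
  labs <- class96_labels()
  w <- rep((1 - purity) / 96, 96)
  hot <- grepl("\\[C>T\\]|\\[T>C\\]", labs)
  w[hot] <- w[hot] + purity / sum(hot)
  signature_profile_new(w, label = "background transitions (synthetic)")
}

#' Read / write signature matrices in COSMIC v2 CSV layout
#'
#' The layout has one row per class with columns \code{SubType} (e.g.
#' \code{"C>A"}), \code{Trinucleotide} (e.g. \code{"ACA"}) and one numeric
#' column per signature.
#'
#' @param path CSV file path.
#' @return \code{read_signature_csv}: a named list of
#'   \code{signature_profile}s, one per numeric column.
#' @export
read_signature_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("SubType", "Trinucleotide")
  if (!all(need %in% names(df))) {
    stop("signature CSV must have SubType and Trinucleotide columns")
  }
  if (nrow(df) != 96L) stop("signature CSV must have exactly 96 rows")
  labs <- paste0(
    substr(df$Trinucleotide, 1, 1), "[", df$SubType, "]",
    substr(df$Trinucleotide, 3, 3)
  )
  if (!setequal(labs, class96_labels())) {
    stop("signature CSV rows do not cover the 96 classes")
  }
  value_cols <- setdiff(names(df), need)
  out <- lapply(value_cols, function(cn) {
    w <- df[[cn]]
    names(w) <- labs
    signature_profile_new(w, label = cn)
  })
  names(out) <- value_cols
  out
}

#' @rdname read_signature_csv
#' @param profiles Named list of \code{signature_profile}s (or one profile).
#' @export
write_signature_csv <- function(profiles, path) {
  if (inherits(profiles, "signature_profile")) {
    profiles <- stats::setNames(list(profiles), attr(profiles, "label"))
  }
  labs <- class96_labels()
  df <- data.frame(
    SubType = substr(labs, 3, 5),
    Trinucleotide = paste0(substr(labs, 1, 1), substr(labs, 3, 3), substr(labs, 7, 7)),
    check.names = FALSE
  )
  for (nm in names(profiles)) df[[nm]] <- as.numeric(profiles[[nm]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Per-stage signature decomposition of an SNV timeline
#'
#' Partitions SNVs into the reprogramming-timeline stages and profiles each:
#' stage 1 are pre-existing mutations already detectable in the parental
#' somatic cells; stage 2 are bona fide de novo mutations that arose just
#' after the onset of lineage conversion (parent-clone VAF in
#' \code{stage2_window}, default 1--25\%); stage 3 arose during prolonged
#' culture (VAF below 1\%); the clone-wide ~50\%-VAF set is reported
#' separately because it cannot be demarcated as de novo or pre-existing
#' from VAF alone.
#'
#' @param snvs Data frame with columns \code{ref}, \code{alt},
#'   \code{context}, \code{vaf} (parent-clone VAF estimate) and optionally
#'   \code{censored}.
#' @param parental_vaf Numeric vector (same length) of VAF estimates in the
#'   parental somatic cells, or NULL if unavailable (stage 1 then empty).
#' @param stage2_window,stage3_max,fifty_window Stage VAF boundaries.
#' @param parental_min Minimum parental-somatic VAF to call a mutation
#'   pre-existing.
#' @param references Named list of \code{signature_profile}s to compare
#'   against; defaults to the bundled synthetic references.
#' @return List with \code{stages} (named list of row-index vectors),
#'   \code{profiles} (per-stage \code{signature_profile}, NULL when a stage
#'   is empty), \code{n} per stage, and \code{cosine} (stage x reference
#'   matrix) with \code{top_match} per stage.
#' @export
stage_profiles <- function(snvs, parental_vaf = NULL,
                           stage2_window = c(0.01, 0.25),
                           stage3_max = 0.01,
                           fifty_window = c(0.35, 0.65),
                           parental_min = 0.05,
                           references = list(
                             sig17 = sig17_like(),
                             sig18 = sig18_like(),
                             background = background_transition_signature()
                           )) {
  stopifnot(is.data.frame(snvs), !is.null(snvs$vaf))
  n <- nrow(snvs)
  censored <- if (!is.null(snvs$censored)) snvs$censored else rep(FALSE, n)
  pre <- if (is.null(parental_vaf)) rep(FALSE, n) else parental_vaf >= parental_min
  vaf <- snvs$vaf
  stages <- list(
    stage1 = which(pre),
    stage2 = which(!pre & !censored &
                     vaf >= stage2_window[1] & vaf <= stage2_window[2]),
    stage3 = which(!pre & !censored & vaf < stage3_max),
    fifty_pct = which(!pre & !censored &
                        vaf >= fifty_window[1] & vaf <= fifty_window[2])
  )
  profiles <- lapply(names(stages), function(st) {
    idx <- stages[[st]]
    if (length(idx) == 0L) return(NULL)
    signature_profile(snvs[idx, , drop = FALSE], label = st)
  })
  names(profiles) <- names(stages)
  cosine <- t(vapply(profiles, function(p) {
    if (is.null(p)) return(rep(NA_real_, length(references)))
    vapply(references, function(r) cosine_similarity(p, r), numeric(1))
  }, numeric(length(references))))
  colnames(cosine) <- names(references)
  top <- apply(cosine, 1, function(row) {
    if (all(is.na(row))) NA_character_ else names(references)[which.max(row)]
  })
  list(
    stages = stages,
    profiles = profiles,
    n = vapply(stages, length, integer(1)),
    cosine = cosine,
    top_match = top
  )
}
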