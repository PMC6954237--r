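#' Read a variant table from VCF or TSV
#'
#' Normalises either format to the internal variant table (1-based,
#' fully-closed coordinates, as in VCF): columns \code{site}, \code{ref},
#' \code{alt}, \code{depth}, \code{alt_count}, \code{chrom_class}, plus
#' any extra columns carried through. VCF input (read with \pkg{vcfR})
#' must provide depth and alt count through the INFO keys \code{DP} and
#' \code{AO}; TSV input must have the internal column names. Malformed
#' TSV records are collected into an error report with line numbers; the
#' read aborts if more than 1\% of records are malformed.
#'
#' @param path File path.
#' @param format \code{"vcf"} or \code{"tsv"}; guessed from the extension
#'   by default.
#' @return Variant data frame; attribute \code{errors} holds the
#'   malformed-record report (data frame: line, message), if any.
#' @export
read_variants <- function(path, format = c("auto", "vcf", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf$", path, ignore.case = TRUE)) "vcf" else "tsv"
  }
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "vcf") read_variants_vcf(path) else read_variants_tsv(path)
}

read_variants_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  dp <- suppressWarnings(as.integer(vcfR::extract.info(v, "DP")))
  ao <- suppressWarnings(as.integer(vcfR::extract.info(v, "AO")))
  if (all(is.na(dp))) stop("VCF is missing the required INFO field: DP (depth)")
  if (all(is.na(ao))) stop("VCF is missing the required INFO field: AO (alt count)")
  out <- data.frame(
    chrom = fix$CHROM,
    site = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT,
    depth = dp, alt_count = ao,
    chrom_class = ifelse(fix$CHROM %in% c("X", "Y", "chrX", "chrY"),
                         "hemizygous", "autosome"),
    stringsAsFactors = FALSE
  )
  ctx <- vcfR::extract.info(v, "CONTEXT")
  if (!all(is.na(ctx))) out$context <- ctx
  gen <- suppressWarnings(as.integer(vcfR::extract.info(v, "GT_GEN")))
  if (!all(is.na(gen))) out$generation <- gen
  info_raw <- vcfR::getINFO(v)
  out$is_burst <- grepl("(^|;)BURST(;|$)", info_raw)
  out
}

read_variants_tsv <- function(path) {
  lines <- readLines(path)
  lines <- sub("\r$", "", lines)       # tolerate CRLF
  lines <- lines[nzchar(lines)]
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  need <- c("site", "ref", "alt", "depth", "alt_count")
  missing <- setdiff(need, header)
  if (length(missing) > 0L) {
    stop("TSV is missing required columns: ", paste(missing, collapse = ", "))
  }
  body <- lines[-1]
  fields <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != length(header))
  errors <- NULL
  if (length(bad) > 0L) {
    errors <- data.frame(
      line = bad + 1L,
      message = sprintf("expected %d fields, found %d",
                        length(header), lengths(fields)[bad]),
      stringsAsFactors = FALSE
    )
    if (length(bad) / max(1L, length(body)) > 0.01) {
      stop(sprintf("%d of %d records malformed (> 1%%); first at line %d",
                   length(bad), length(body), bad[1] + 1L))
    }
    fields <- fields[-bad]
  }
  df <- as.data.frame(do.call(rbind, fields), stringsAsFactors = FALSE)
  names(df) <- header
  for (cn in intersect(c("site", "depth", "alt_count", "generation"), header)) {
    df[[cn]] <- as.integer(df[[cn]])
  }
  for (cn in intersect(c("vaf", "true_vaf"), header)) {
    df[[cn]] <- as.numeric(df[[cn]])
  }
  if (!"chrom_class" %in% header) df$chrom_class <- "autosome"
  attr(df, "errors") <- errors
  df
}

#' Write a variant table as TSV or VCF v4.2
#'
#' VCF output places depth, alt count, origin generation, burst flag and
#' trinucleotide context in the INFO column (keys \code{DP}, \code{AO},
#' \code{GT_GEN}, \code{BURST}, \code{CONTEXT}).
#'
#' @param variants Variant data frame (VCF output additionally uses
#'   \code{generation}, \code{is_burst}, \code{context} when present).
#' @param path Output path.
#' @param contig Contig name used for VCF records.
#' @param contig_length Contig length for the VCF header.
#' @return The path, invisibly.
#' @export
write_variants_tsv <- function(variants, path) {
  utils::write.table(variants, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_variants_tsv
#' @export
write_variants_vcf <- function(variants, path, contig = "sim1",
                               contig_length = NULL) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=burstline",
    if (!is.null(contig_length)) {
      sprintf("##contig=<ID=%s,length=%d>", contig, as.integer(contig_length))
    } else sprintf("##contig=<ID=%s>", contig),
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total read depth\">",
    "##INFO=<ID=AO,Number=1,Type=Integer,Description=\"Alternate allele read count\">",
    "##INFO=<ID=GT_GEN,Number=1,Type=Integer,Description=\"Ground-truth origin generation\">",
    "##INFO=<ID=BURST,Number=0,Type=Flag,Description=\"Arose inside the hypermutation window\">",
    "##INFO=<ID=CONTEXT,Number=1,Type=String,Description=\"Trinucleotide context\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  info <- vapply(seq_len(nrow(variants)), function(i) {
    parts <- character(0)
    if (!is.null(variants$depth)) parts <- c(parts, paste0("DP=", variants$depth[i]))
    if (!is.null(variants$alt_count)) parts <- c(parts, paste0("AO=", variants$alt_count[i]))
    if (!is.null(variants$generation)) parts <- c(parts, paste0("GT_GEN=", variants$generation[i]))
    if (isTRUE(variants$is_burst[i])) parts <- c(parts, "BURST")
    if (!is.null(variants$context)) parts <- c(parts, paste0("CONTEXT=", variants$context[i]))
    if (length(parts) == 0L) "." else paste(parts, collapse = ";")
  }, character(1))
  ids <- if (!is.null(variants$id)) variants$id else rep(".", nrow(variants))
  records <- sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\t%s",
                     contig, variants$site, ids, variants$ref, variants$alt,
                     info)
  writeLines(c(header, records), path)
  invisible(path)
}

#' Write read-count observations as TSV
#' @param obs Data frame from \code{\link{sample_reads}}.
#' @param path Output path.
#' @export
write_readcounts_tsv <- function(obs, path) {
  utils::write.table(
    obs[, c("site", "id", "sample", "assay", "total_reads", "alt_reads")],
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

config_hash <- function(config) {
  plain <- unclass(config)
  plain$burst_signature <- as.numeric(plain$burst_signature)
  plain$background_signature <- as.numeric(plain$background_signature)
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(plain, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Run the full inference pipeline on a simulated clone
#'
#' Chains every stage end to end: simulate a clonal expansion, sequence
#' the parent clone (WGS + ultra-deep amplicon) and the parental somatic
#' cells, derive sublines and call their SNVs through the WGS filter
#' chain, decompose shared/specific SNVs and reconstruct the
#' developmental tree, estimate parent-clone VAFs and classify timing
#' groups, test burst versus continuous accumulation, and profile
#' mutational signatures per stage. All outputs are written under
#' \code{out_dir} and indexed by a JSON run manifest.
#'
#' @param config A \code{sim_config}.
#' @param out_dir Output directory (created if needed).
#' @param seed Seed for the whole run.
#' @param n_sublines Number of sublines derived.
#' @param skip_signature Omit the signature stage.
#' @return The run manifest (list), invisibly written to
#'   \code{manifest.json}.
#' @export
run_pipeline <- function(config = sim_config(), out_dir = tempfile("burstline_"),
                         seed = 1L, n_sublines = 4L, skip_signature = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  config$seed <- NULL
  paths <- list()
  counts <- list()

  # -- simulate ------------------------------------------------------------
  mset <- simulate_clone(config)
  paths$variants_vcf <- file.path(out_dir, "clone_mutations.vcf")
  write_variants_vcf(as.data.frame(mset), paths$variants_vcf,
                     contig_length = config$genome_length)
  counts$simulated <- nrow(mset)

  # -- sequencing ----------------------------------------------------------
  parent_wgs <- sample_reads(mset, config, "wgs", "parent")
  parent_amp <- sample_reads(mset, config, "amplicon", "parent")
  somatic_amp <- sample_reads(mset, config, "amplicon", "parental_somatic")
  paths$readcounts <- file.path(out_dir, "readcounts.tsv")
  write_readcounts_tsv(rbind(parent_wgs, parent_amp, somatic_amp),
                       paths$readcounts)

  # -- sublines + filters --------------------------------------------------
  G <- config$generations
  leaves <- floor((seq_len(n_sublines) - 0.5) / n_sublines * 2^G)
  subline_calls <- lapply(leaves, function(l) {
    sl <- derive_subline(mset, config, l)
    obs <- sample_reads(sl, config, "wgs", "subline")
    vars <- data.frame(
      site = sl$site, ref = sl$ref, alt = sl$alt,
      depth = obs$total_reads, alt_count = obs$alt_reads,
      chrom_class = ifelse(sl$zygosity == "hemizygous", "hemizygous",
                           "autosome"),
      id = sl$id, parent_id = sl$parent_id,
      stringsAsFactors = FALSE
    )
    filter_snvs(vars, filter_policy(), NULL)$kept
  })
  called_parent_ids <- lapply(subline_calls, function(k) {
    k$parent_id[!is.na(k$parent_id)]
  })
  all_ids <- sort(unique(unlist(called_parent_ids)))
  counts$panel_snvs <- length(all_ids)
  mat <- vapply(called_parent_ids, function(ids) all_ids %in% ids,
                logical(length(all_ids)))
  mat <- matrix(mat, nrow = length(all_ids),
                dimnames = list(all_ids, sprintf("SL%d", seq_len(n_sublines))))
  parent_obs <- data.frame(id = parent_wgs$id,
                           total_reads = parent_wgs$total_reads,
                           alt_reads = parent_wgs$alt_reads)
  panel <- subline_panel(mat, parent_obs = parent_obs,
                         snv_meta = as.data.frame(mset))
  paths$panel <- file.path(out_dir, "subline_panel.tsv")
  utils::write.table(cbind(id = rownames(mat), as.data.frame(mat)),
                     paths$panel, sep = "\t", quote = FALSE, row.names = FALSE)

  # -- tree ----------------------------------------------------------------
  venn <- venn_decompose(panel)
  tree <- build_tree(panel)
  paths$tree <- file.path(out_dir, "developmental_tree.nwk")
  writeLines(tree$newick, paths$tree)
  timeline_edges <- edge_timeline(tree, parent_obs,
                                  snv_meta = as.data.frame(mset))
  paths$edge_timeline <- file.path(out_dir, "edge_timeline.tsv")
  utils::write.table(timeline_edges, paths$edge_timeline, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  counts$tree_incompatible <- length(tree$incompatible)

  # -- timing --------------------------------------------------------------
  # de novo SNVs only: drop sites already present in the parental somatic
  # cells (the parental-sharing exclusion), then time the remainder
  som_est <- estimate_vaf(somatic_amp, vaf_floor = config$vaf_floor)
  de_novo <- som_est$vaf < 0.05
  amp <- cbind(parent_amp,
               ref = mset$ref, alt = mset$alt, context = mset$context)
  report <- timeline_report(amp[de_novo, , drop = FALSE],
                            vaf_floor = config$vaf_floor)
  paths$timeline <- file.path(out_dir, "timeline.tsv")
  write_variants_tsv(report$calls, paths$timeline)
  counts$group_I <- sum(report$calls$group == "I")
  counts$group_II <- sum(report$calls$group == "II")
  counts$censored <- sum(report$calls$group == "censored")
  verdict <- list(
    verdict = report$burst$verdict,
    window = report$burst$window,
    delta_aic = report$burst$delta_aic
  )
  paths$verdict <- file.path(out_dir, "burst_verdict.json")
  jsonlite::write_json(verdict, paths$verdict, auto_unbox = TRUE, digits = NA)

  # -- signatures ----------------------------------------------------------
  if (!skip_signature) {
    all_est <- estimate_vaf(amp, vaf_floor = config$vaf_floor)
    all_calls <- classify_group(all_est)
    stages <- stage_profiles(all_calls, parental_vaf = som_est$vaf)
    prof_list <- Filter(Negate(is.null), stages$profiles)
    if (length(prof_list) > 0L) {
      paths$stage_profiles <- file.path(out_dir, "stage_profiles.csv")
      write_signature_csv(prof_list, paths$stage_profiles)
    }
    paths$stage_cosine <- file.path(out_dir, "stage_cosine.json")
    jsonlite::write_json(
      list(n = as.list(stages$n), top_match = as.list(stages$top_match)),
      paths$stage_cosine, auto_unbox = TRUE, digits = NA
    )
    counts$stage_n <- stages$n
  }

  manifest <- list(
    tool = "burstline",
    version = as.character(utils::packageVersion("burstline")),
    seed = seed,
    config_hash = config_hash(config),
    paths = paths,
    counts = counts,
    burst_verdict = verdict
  )
  paths$manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA)
  invisible(manifest)
}
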