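#' Build a subline presence/absence panel
#'
#' A panel records, for each SNV discovered in any single-cell-derived
#' subline, whether it was called in each subline, together with the
#' parent clone's read counts at the site (used to estimate the SNV's VAF
#' in the parent population).
#'
#' @param matrix Logical matrix, SNVs in rows (rownames = SNV ids),
#'   sublines in columns (colnames = subline ids).
#' @param parent_obs Optional data frame with \code{id},
#'   \code{total_reads}, \code{alt_reads} for the parent clone.
#' @param snv_meta Optional data frame of per-SNV annotation (\code{id},
#'   \code{ref}, \code{alt}, \code{context}, ...).
#' @return A \code{subline_panel}.
#' @export
subline_panel <- function(matrix, parent_obs = NULL, snv_meta = NULL) {
  matrix <- as.matrix(matrix)
  storage.mode(matrix) <- "logical"
  if (is.null(rownames(matrix))) rownames(matrix) <- sprintf("m%05d", seq_len(nrow(matrix)))
  if (is.null(colnames(matrix))) colnames(matrix) <- sprintf("SL%d", seq_len(ncol(matrix)))
  if (any(rowSums(matrix) == 0L)) {
    stop("panel contains SNVs absent from every subline")
  }
  structure(list(matrix = matrix, parent_obs = parent_obs,
                 snv_meta = snv_meta),
            class = "subline_panel")
}

#' Build the panel observed from simulated sublines
#'
#' Derives \code{n_sublines} sublines from distinct final cells of a
#' simulated clone and records which parent-clone mutations each subline
#' inherited (noiseless calls: a mutation is "called" iff carried).
#'
#' @param mset A \code{lineage_mutation_set}.
#' @param config Its \code{sim_config}.
#' @param n_sublines Number of sublines.
#' @param leaf_indices Founding cells; default: evenly spread across the
#'   final population so sublines sample distinct early subtrees.
#' @param parent_obs Optional parent read counts to attach.
#' @return A \code{subline_panel} over the mutations carried by at least
#'   one subline; attribute \code{leaf_indices} records the founders.
#' @export
panel_from_simulation <- function(mset, config, n_sublines = 4L,
                                  leaf_indices = NULL, parent_obs = NULL) {
  G <- config$generations
  if (is.null(leaf_indices)) {
    leaf_indices <- floor((seq_len(n_sublines) - 0.5) / n_sublines * 2^G)
  }
  calls <- vapply(leaf_indices, function(l) leaf_carries(mset, l),
                  logical(nrow(mset)))
  calls <- base::matrix(calls, nrow = nrow(mset),
                        dimnames = list(mset$id,
                                        sprintf("SL%d", seq_along(leaf_indices))))
  keep <- rowSums(calls) > 0L
  po <- if (!is.null(parent_obs)) parent_obs[match(mset$id[keep], parent_obs$id), ]
  p <- subline_panel(calls[keep, , drop = FALSE], parent_obs = po,
                     snv_meta = as.data.frame(mset)[keep, , drop = FALSE])
  attr(p, "leaf_indices") <- leaf_indices
  p
}

#' Venn decomposition of a subline panel
#'
#' Maps every SNV to the exact subset of sublines carrying it and counts
#' SNVs per subset — the Venn-diagram view of shared versus
#' subline-specific mutations.
#'
#' @param panel A \code{subline_panel}.
#' @return List with \code{membership} (data frame: SNV id, carrier
#'   pattern string, carrier count) and \code{counts} (named integer
#'   vector per observed subset pattern; names list carrier sublines
#'   joined by \code{"&"}).
#' @export
venn_decompose <- function(panel) {
  m <- panel$matrix
  if (ncol(m) < 2L) stop("venn decomposition needs at least 2 sublines")
  pattern <- apply(m, 1L, function(r) paste(as.integer(r), collapse = ""))
  subset_name <- apply(m, 1L, function(r) {
    paste(sort(colnames(m)[r]), collapse = "&")
  })
  membership <- data.frame(
    id = rownames(m), pattern = pattern, subset = subset_name,
    n_carriers = as.integer(rowSums(m)), stringsAsFactors = FALSE
  )
  counts <- table(subset_name)
  counts <- stats::setNames(as.integer(counts), names(counts))
  list(membership = membership, counts = counts)
}

clade_key <- function(members) paste(sort(members), collapse = "|")

#' Reconstruct the developmental tree from a subline panel
#'
#' SNV presence across sublines is a binary character with known ancestral
#' state (absent in the clone founder), so a conflict-free panel admits a
#' rooted perfect phylogeny: two SNVs are compatible iff their carrier
#' sets are nested or disjoint. Incompatible SNVs (call errors, recurrent
#' sites) are removed greedily — highest pairwise-conflict degree first,
#' ties broken by lower parent-clone VAF so the noisier call is
#' sacrificed — and flagged, and the tree is built on the remainder with
#' every SNV attached to the edge above the clade of its carriers.
#'
#' @param panel A \code{subline_panel} with >= 2 sublines.
#' @return A \code{developmental_tree}: list with \code{leaves},
#'   \code{clades} (list of subline-id vectors, one per node),
#'   \code{edge_snvs} (named list, clade key -> SNV ids on the edge above
#'   that clade), \code{incompatible} (flagged SNV ids), \code{newick}
#'   and \code{phylo} (an \pkg{ape} tree).
#' @export
build_tree <- function(panel) {
  m <- panel$matrix
  if (ncol(m) < 2L) stop("tree reconstruction needs at least 2 sublines")
  sets <- apply(m, 1L, function(r) colnames(m)[r], simplify = FALSE)

  conflicts <- function(a, b) {
    i <- length(intersect(a, b))
    i > 0L && i < length(a) && i < length(b)
  }
  n <- nrow(m)
  conflict_mat <- base::matrix(FALSE, n, n)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      if (conflicts(sets[[i]], sets[[j]])) {
        conflict_mat[i, j] <- conflict_mat[j, i] <- TRUE
      }
    }
  }
  parent_vaf <- rep(NA_real_, n)
  if (!is.null(panel$parent_obs)) {
    po <- panel$parent_obs
    idx <- match(rownames(m), po$id)
    parent_vaf <- po$alt_reads[idx] / po$total_reads[idx]
  }
  active <- rep(TRUE, n)
  repeat {
    deg <- rowSums(conflict_mat[, active, drop = FALSE]) * active
    if (all(deg == 0)) break
    worst <- which(deg == max(deg))
    if (length(worst) > 1L && any(!is.na(parent_vaf[worst]))) {
      worst <- worst[order(parent_vaf[worst], na.last = FALSE)]
    }
    active[worst[1L]] <- FALSE
  }
  incompatible <- rownames(m)[!active]

  # laminar family of carrier sets -> containment tree
  leaves <- colnames(m)
  keys <- vapply(sets, clade_key, character(1))
  clades <- list()
  for (i in which(active)) clades[[keys[i]]] <- sets[[i]]
  clades[[clade_key(leaves)]] <- leaves
  for (l in leaves) clades[[clade_key(l)]] <- l
  sizes <- vapply(clades, length, integer(1))

  parent_of <- function(key) {
    members <- clades[[key]]
    sup <- names(clades)[vapply(clades, function(c2) {
      length(c2) > length(members) && all(members %in% c2)
    }, logical(1))]
    if (length(sup) == 0L) return(NA_character_)
    sup[which.min(sizes[sup])]
  }
  parents <- vapply(names(clades), parent_of, character(1))

  edge_snvs <- lapply(names(clades), function(k) {
    rownames(m)[active & keys == k]
  })
  names(edge_snvs) <- names(clades)

  children_of <- function(key) names(clades)[!is.na(parents) & parents == key]
  to_newick <- function(key) {
    ch <- children_of(key)
    if (length(ch) == 0L) return(clades[[key]])
    paste0("(", paste(vapply(ch, to_newick, character(1)), collapse = ","), ")")
  }
  root_key <- clade_key(leaves)
  newick <- paste0(to_newick(root_key), ";")
  structure(
    list(leaves = leaves, clades = clades, parents = parents,
         edge_snvs = edge_snvs, incompatible = incompatible,
         newick = newick, phylo = ape::read.tree(text = newick)),
    class = "developmental_tree"
  )
}

#' @export
print.developmental_tree <- function(x, ...) {
  cat("<developmental_tree>", length(x$leaves), "sublines\n")
  cat("  ", x$newick, "\n")
  n_assigned <- sum(lengths(x$edge_snvs))
  cat(sprintf("  %d SNVs on edges, %d flagged incompatible\n",
              n_assigned, length(x$incompatible)))
  invisible(x)
}

#' Check pairwise compatibility of a panel (no conflict removal)
#' @param panel A \code{subline_panel}.
#' @return TRUE iff every pair of carrier sets is nested or disjoint.
#' @export
is_perfect_phylogeny <- function(panel) {
  m <- panel$matrix
  sets <- apply(m, 1L, function(r) colnames(m)[r], simplify = FALSE)
  n <- length(sets)
  if (n < 2L) return(TRUE)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    a <- sets[[i]]; b <- sets[[j]]
    k <- length(intersect(a, b))
    if (k > 0L && k < length(a) && k < length(b)) return(FALSE)
  }
  TRUE
}

#' Per-edge timeline summary of a developmental tree
#'
#' For each edge (clade) of the tree, summarises the SNVs assigned to it:
#' count, mean VAF in the parent clone, transition/transversion counts,
#' and the fraction that conventional parent-clone WGS would have kept
#' under the SNV filter policy — shared (deep) edges carry high-VAF SNVs
#' detectable by conventional WGS while subline-specific edges carry SNVs
#' conventional WGS misses.
#'
#' @param tree A \code{developmental_tree}.
#' @param parent_obs Parent-clone read counts (\code{id},
#'   \code{total_reads}, \code{alt_reads}); if NULL, taken from nothing
#'   and VAF columns are NA.
#' @param snv_meta Per-SNV \code{ref}/\code{alt} annotation for ts/tv.
#' @param policy \code{filter_policy} used for the "detected by
#'   conventional WGS" fraction.
#' @return Data frame, one row per edge: clade key, number of carrier
#'   sublines, SNV count, mean parent VAF, ts, tv, detected fraction.
#' @export
edge_timeline <- function(tree, parent_obs = NULL, snv_meta = NULL,
                          policy = filter_policy()) {
  rows <- lapply(names(tree$clades), function(key) {
    ids <- tree$edge_snvs[[key]]
    out <- data.frame(
      clade = key, n_sublines = length(tree$clades[[key]]),
      n_snvs = length(ids), mean_parent_vaf = NA_real_,
      ts = NA_integer_, tv = NA_integer_, detected_fraction = NA_real_,
      stringsAsFactors = FALSE
    )
    if (length(ids) == 0L) return(out)
    if (!is.null(parent_obs)) {
      idx <- match(ids, parent_obs$id)
      vafs <- parent_obs$alt_reads[idx] / parent_obs$total_reads[idx]
      out$mean_parent_vaf <- mean(vafs, na.rm = TRUE)
      vars <- data.frame(
        site = seq_along(ids), ref = "C", alt = "T",
        depth = parent_obs$total_reads[idx],
        alt_count = parent_obs$alt_reads[idx],
        chrom_class = "autosome", stringsAsFactors = FALSE
      )
      if (!is.null(snv_meta)) {
        mi <- match(ids, snv_meta$id)
        vars$ref <- snv_meta$ref[mi]
        vars$alt <- snv_meta$alt[mi]
      }
      res <- filter_snvs(vars, policy, NULL)
      out$detected_fraction <- nrow(res$kept) / length(ids)
    }
    if (!is.null(snv_meta)) {
      mi <- match(ids, snv_meta$id)
      tt <- tstv(snv_meta[mi[!is.na(mi)], , drop = FALSE])
      out$ts <- tt$ts; out$tv <- tt$tv
    }
    out
  })
  do.call(rbind, rows)
}
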