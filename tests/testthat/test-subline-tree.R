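panel_from_matrix <- function(rows, sublines = NULL) {
  m <- do.call(rbind, lapply(rows, function(r) as.integer(strsplit(r, "")[[1]]) == 1L))
  if (is.null(sublines)) sublines <- LETTERS[seq_len(ncol(m))]
  colnames(m) <- sublines
  rownames(m) <- sprintf("m%05d", seq_along(rows))
  subline_panel(m)
}

test_that("venn decomposition maps SNVs to exact carrier subsets", {
  p <- panel_from_matrix(c("111", "110", "100", "001"))
  venn <- venn_decompose(p)
  expect_identical(sort(unname(venn$membership$n_carriers)), c(1L, 1L, 2L, 3L))
  expect_equal(unname(venn$counts["A&B&C"]), 1L)
  expect_equal(unname(venn$counts["A&B"]), 1L)
  expect_equal(unname(venn$counts["A"]), 1L)
  expect_equal(unname(venn$counts["C"]), 1L)
  # an SNV present everywhere lands in the shared-by-all class
  expect_identical(venn$membership$subset[venn$membership$pattern == "111"],
                   "A&B&C")
})

test_that("venn decomposition is invariant to row and column permutation", {
  set.seed(501)
  m <- matrix(stats::runif(60) < 0.5, nrow = 15,
              dimnames = list(sprintf("m%05d", 1:15), LETTERS[1:4]))
  m[rowSums(m) == 0L, 1] <- TRUE
  v1 <- venn_decompose(subline_panel(m))
  perm_rows <- sample(nrow(m)); perm_cols <- sample(ncol(m))
  v2 <- venn_decompose(subline_panel(m[perm_rows, perm_cols]))
  expect_identical(sort(table(v1$membership$subset)),
                   sort(table(v2$membership$subset)))
  expect_identical(sort(v1$counts), sort(v2$counts))
})

test_that("a compatible matrix yields the textbook perfect phylogeny", {
  p <- panel_from_matrix(c("1111", "1100", "0011"))
  expect_true(is_perfect_phylogeny(p))
  tree <- build_tree(p)
  expect_length(tree$incompatible, 0L)
  clades <- Filter(function(x) length(x) > 1, tree$clades)
  expect_setequal(vapply(clades, paste, collapse = "", character(1)),
                  c("ABCD", "AB", "CD"))
  expect_identical(tree$edge_snvs[["A|B"]], "m00002")
  expect_identical(tree$edge_snvs[["C|D"]], "m00003")
  expect_identical(tree$edge_snvs[["A|B|C|D"]], "m00001")
  ph <- tree$phylo
  expect_s3_class(ph, "phylo")
  expect_setequal(ph$tip.label, c("A", "B", "C", "D"))
})

test_that("noiseless simulated panels reconstruct the true division tree", {
  set.seed(502)
  n_ok <- 0L
  for (i in 1:20) {
    cfg <- small_config(generations = sample(5:8, 1),
                        mu_burst = 3, n_preexisting = 5)
    mset <- simulate_clone(cfg)
    G <- attr(mset, "config")$generations
    n_sub <- 4L
    leaves <- floor((seq_len(n_sub) - 0.5) / n_sub * 2^G)
    panel <- panel_from_simulation(mset, cfg, leaf_indices = leaves)
    tree <- build_tree(panel)
    expect_length(tree$incompatible, 0L)
    # true clades of the division tree restricted to the sampled leaves
    true_clades <- unique(Filter(function(x) length(x) >= 1, lapply(
      unlist(lapply(0:G, function(k) lapply(0:(2^k - 1), function(i) {
        which(leaves %/% 2^(G - k) == i)
      })), recursive = FALSE),
      function(idx) sprintf("SL%d", idx)
    )))
    true_keys <- vapply(true_clades, function(x) paste(sort(x), collapse = "|"),
                        character(1))
    rec_keys <- vapply(tree$clades, function(x) paste(sort(x), collapse = "|"),
                       character(1))
    # every reconstructed clade is a genuine clade of the division tree
    expect_true(all(rec_keys %in% true_keys))
    # and SNV carrier sets are placed on the edge of exactly their clade
    venn <- venn_decompose(panel)
    for (key in names(tree$edge_snvs)) {
      ids <- tree$edge_snvs[[key]]
      if (length(ids) == 0L) next
      pats <- venn$membership$subset[match(ids, venn$membership$id)]
      expect_true(all(vapply(strsplit(pats, "&", fixed = TRUE),
                             function(x) paste(sort(x), collapse = "|"),
                             character(1)) == key))
    }
    n_ok <- n_ok + 1L
  }
  expect_equal(n_ok, 20L)
})

test_that("a single flipped call is the one flagged incompatible", {
  p <- panel_from_matrix(c("1111", "1100", "1100", "0011", "0011", "1000"))
  m <- p$matrix
  m["m00004", "B"] <- TRUE       # flip one cell: CD-SNV now claims B too
  p_bad <- subline_panel(m)
  expect_false(is_perfect_phylogeny(p_bad))
  tree <- build_tree(p_bad)
  expect_identical(tree$incompatible, "m00004")
  # the rest of the tree is intact
  clades <- Filter(function(x) length(x) > 1, tree$clades)
  expect_setequal(vapply(clades, paste, collapse = "", character(1)),
                  c("ABCD", "AB", "CD"))
})

test_that("pairwise compatibility equals the sorted nested-or-disjoint check", {
  sorted_check <- function(m) {
    # independent formulation: sort columns of the transposed character
    # matrix by carrier count; every pair must be nested or disjoint
    sets <- apply(m, 1, function(r) which(r), simplify = FALSE)
    sets <- sets[order(-lengths(sets))]
    for (i in seq_along(sets)) for (j in seq_len(i - 1L)) {
      ov <- length(intersect(sets[[i]], sets[[j]]))
      if (ov > 0L && ov < length(sets[[i]])) return(FALSE)
    }
    TRUE
  }
  set.seed(503)
  for (i in 1:40) {
    n_leaf <- sample(3:6, 1)
    m <- matrix(stats::runif(n_leaf * 8) < 0.4, nrow = 8,
                dimnames = list(sprintf("m%05d", 1:8),
                                LETTERS[seq_len(n_leaf)]))
    m[rowSums(m) == 0L, 1] <- TRUE
    expect_identical(is_perfect_phylogeny(subline_panel(m)), sorted_check(m))
  }
})

test_that("edge timelines separate shared from subline-specific SNVs", {
  set.seed(504)
  cfg <- small_config(generations = 8, mu_burst = 4, mu_background = 0.3,
                      n_preexisting = 10)
  mset <- simulate_clone(cfg)
  parent_wgs <- sample_reads(mset, cfg, "wgs", "parent")
  parent_obs <- data.frame(id = parent_wgs$id,
                           total_reads = parent_wgs$total_reads,
                           alt_reads = parent_wgs$alt_reads)
  panel <- panel_from_simulation(mset, cfg, n_sublines = 4L,
                                 parent_obs = parent_obs)
  tree <- build_tree(panel)
  tl <- edge_timeline(tree, parent_obs, snv_meta = as.data.frame(mset))
  root <- tl[tl$n_sublines == 4L & tl$n_snvs > 0L, ]
  leafs <- tl[tl$n_sublines == 1L & tl$n_snvs > 0L, ]
  # root-edge SNVs are clone-wide: parent VAF near 50%
  expect_true(all(abs(root$mean_parent_vaf - 0.5) < 0.1))
  # subline-specific SNVs sit far below, mostly invisible to parent WGS
  expect_true(mean(leafs$mean_parent_vaf) < 0.15)
  expect_true(mean(root$detected_fraction) >
                mean(leafs$detected_fraction, na.rm = TRUE))
  # an empty edge yields an empty summary row
  empty <- tl[tl$n_snvs == 0L, ]
  if (nrow(empty) > 0L) {
    expect_true(all(is.na(empty$mean_parent_vaf)))
  }
})

test_that("degenerate panels are rejected", {
  expect_error(build_tree(panel_from_matrix(c("1"), "A")), "at least 2")
  expect_error(venn_decompose(panel_from_matrix(c("1"), "A")), "at least 2")
  expect_error(subline_panel(matrix(FALSE, 1, 2)), "absent from every")
})
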