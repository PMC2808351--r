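test_that("detectability needs 5 of 6 present replicates in at least one dataset", {
  mk <- function(present) {
    v <- matrix(rnorm(6), 1, 6)
    if (present < 6) v[1, seq_len(6 - present)] <- NA
    v
  }
  mapping <- resolve_best_match(data.frame(
    clone_id = c("c1", "c2"), gene_id = c("gA", "gB"), score = 1,
    stringsAsFactors = FALSE))
  # gA's clone is 5/6 in one dataset only; gB's clone is 4/6 everywhere
  d1 <- ratio_matrix(rbind(mk(5), mk(4)), clone_ids = c("c1", "c2"))
  d2 <- ratio_matrix(rbind(mk(3), mk(4)), clone_ids = c("c1", "c2"))
  u <- detectable_universe(list(d1, d2), mapping)
  expect_true("gA" %in% u)
  expect_false("gB" %in% u)
})

test_that("an empty universe refuses downstream overlap testing", {
  mapping <- resolve_best_match(data.frame(
    clone_id = "c1", gene_id = "gA", score = 1, stringsAsFactors = FALSE))
  v <- matrix(NA_real_, 1, 6)
  v[1, 1:2] <- 0
  u <- detectable_universe(list(ratio_matrix(v, clone_ids = "c1")), mapping)
  expect_length(u, 0)
  expect_error(
    pairwise_overlap(gene_list(character(0)), gene_list(character(0)), u),
    "empty universe")
})

test_that("hypergeometric tail matches exhaustive subset enumeration", {
  # zero overlap covers the whole sample space
  expect_identical(hypergeom_upper_tail(0, 3, 4, 10), 1)
  # 2-subsets of a 5-element universe: only 1 of the 10 draws overlaps
  # both elements of a fixed 2-set
  expect_equal(hypergeom_upper_tail(2, 2, 2, 5), 0.1)
  expect_equal(hypergeom_upper_tail(2, 2, 2, 5), oracle_hyper_enum(2, 2, 2, 5))
  # a larger case against the term-by-term pmf oracle
  expect_equal(hypergeom_upper_tail(4, 5, 8, 20),
               oracle_hyper_terms(4, 5, 8, 20), tolerance = 1e-12)
})

test_that("hypergeometric tail validates its domain and is symmetric", {
  expect_error(hypergeom_upper_tail(3, 2, 5, 10), "exceeds min")
  expect_error(hypergeom_upper_tail(1, 5, 11, 10), "universe")
  expect_error(hypergeom_upper_tail(-1, 2, 2, 10), "non-negative")
  expect_equal(hypergeom_upper_tail(3, 6, 9, 30),
               hypergeom_upper_tail(3, 9, 6, 30))
})

test_that("p is monotone in the overlap and in the universe size", {
  p_by_o <- sapply(0:5, hypergeom_upper_tail, n_i = 5, n_j = 8, n_u = 40)
  expect_true(all(diff(p_by_o) <= 0))
  p_by_u <- sapply(20:60, function(nu)
    hypergeom_upper_tail(4, 5, 8, nu))
  expect_true(all(diff(p_by_u) <= 1e-15))
})

test_that("pairwise overlap scores behave at the extremes", {
  u <- gene_universe(sprintf("g%02d", 1:40))
  a <- gene_list(sprintf("g%02d", 1:6), "A")
  b <- gene_list(sprintf("g%02d", 7:12), "B")
  dis <- pairwise_overlap(a, b, u)
  expect_equal(dis$o_ij, 0)
  expect_equal(dis$p_value, 1)
  expect_false(dis$significant)

  same <- pairwise_overlap(a, a, u)
  expect_equal(same$o_ij, 6)
  expect_equal(same$p_value, hypergeom_upper_tail(6, 6, 6, 40))
  expect_true(same$significant)

  expect_error(
    pairwise_overlap(gene_list("not_in_u"), a, u), "not_in_u")
})

test_that("signature-scale overlaps are significant at alpha 0.001", {
  # lists of ~900-1700 genes in a 12,903-gene universe; their pairwise
  # overlap carries the 93-gene three-way signature plus the shared
  # two-way regions, well above the ~124 expected by chance
  u <- gene_universe(sprintf("g%05d", 1:12903))
  shared <- sprintf("g%05d", 1:250)  # 93 signature + 157 two-way genes
  g1 <- gene_list(c(shared, sprintf("g%05d", 301:1720)), "mob")
  g2 <- gene_list(c(shared, sprintf("g%05d", 3001:3708)), "lsc")
  ov <- pairwise_overlap(g1, g2, u, alpha = 0.001)
  expect_equal(ov$o_ij, 250)
  expect_true(ov$significant)
  expect_lt(ov$p_value, 1e-10)
})

test_that("the trinary indicator is the conjunction of its constituents", {
  u <- gene_universe(sprintf("g%03d", 1:200))
  a <- gene_list(sprintf("g%03d", 1:12), "A")
  expect_true(trinary_indicator(a, a, a, u)$indicator)

  b <- gene_list(sprintf("g%03d", 1:12), "B")
  c_ <- gene_list(sprintf("g%03d", 101:112), "C")  # disjoint from a and b
  t3 <- trinary_indicator(a, b, c_, u)
  expect_false(t3$indicator)
  expect_equal(t3$constituents$ik$p_value, 1)

  # exactly two significant pairs and one non-significant pair is false:
  # x shares 10 genes with both y and z, but y and z are disjoint
  x <- gene_list(sprintf("g%03d", 1:20), "X")
  y <- gene_list(sprintf("g%03d", c(1:10, 121:130)), "Y")
  z <- gene_list(sprintf("g%03d", c(11:20, 141:150)), "Z")
  t2 <- trinary_indicator(x, y, z, u)
  expect_true(t2$constituents$ij$significant)
  expect_true(t2$constituents$ik$significant)
  expect_false(t2$constituents$jk$significant)
  expect_equal(t2$constituents$jk$p_value, 1)
  expect_false(t2$indicator)
})

test_that("the trinary indicator is permutation symmetric", {
  u <- gene_universe(sprintf("g%03d", 1:150))
  set.seed(7)
  gl <- lapply(1:3, function(i)
    gene_list(sample(unclass(u), 25), paste0("L", i)))
  base_ind <- trinary_indicator(gl[[1]], gl[[2]], gl[[3]], u)$indicator
  perms <- list(c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  for (pp in perms) {
    expect_equal(
      trinary_indicator(gl[[pp[1]]], gl[[pp[2]]], gl[[pp[3]]], u)$indicator,
      base_ind)
  }
})

test_that("region intersection counts genes and their supporting clones", {
  cfg <- small_config()
  m <- resolve_best_match(generate_clone_library(cfg))
  mapped <- m[!is.na(m$gene_id), ]
  genes_a <- sort(unique(mapped$gene_id))[1:30]
  genes_b <- sort(unique(mapped$gene_id))[16:45]
  lists <- list(gene_list(genes_a, "A"), gene_list(genes_b, "B"))
  clones_a <- mapped$clone_id[mapped$gene_id %in% genes_a]
  clones_b <- mapped$clone_id[mapped$gene_id %in% genes_b]
  reg <- intersect_region(lists, m, list(clones_a, clones_b))
  expect_identical(reg$genes, sort(intersect(genes_a, genes_b)))
  expect_gte(reg$n_clones, reg$n_genes)  # redundancy >= 1

  # a list and its complement intersect to nothing
  u_all <- sort(unique(mapped$gene_id))
  comp <- setdiff(u_all, genes_a)
  reg0 <- intersect_region(list(gene_list(genes_a), gene_list(comp)), m)
  expect_equal(reg0$n_genes, 0)

  expect_error(intersect_region(list(), m), "at least one")
})

test_that("Venn regions partition each comparison's gene list", {
  cfg <- small_config(seed = 37)
  st <- simulate_study(cfg)
  m <- resolve_best_match(st$mapping)
  de <- lapply(st$ratios, sam_de)
  gl <- suppressMessages(
    mapply(directional_gene_lists, de, names(de),
           MoreArgs = list(mapping = m), SIMPLIFY = FALSE))
  cl <- lapply(de, function(d) list(up = d$up_clones, down = d$down_clones))
  vc <- venn_counts(gl, cl, m)
  for (i in seq_along(gl)) {
    for (dir in c("down", "up")) {
      in_regions <- vc$n_genes[vc$direction == dir &
                                 grepl(as.character(i), vc$region)]
      expect_equal(sum(in_regions), length(gl[[i]][[dir]]))
    }
  }
})

test_that("truth-driven Venn counts equal the planted sizes under an oracle DE stage", {
  cfg <- small_config(seed = 41)
  st <- simulate_study(cfg)
  m <- resolve_best_match(st$mapping)
  # no-noise DE oracle: read the truth directly
  gl <- lapply(names(st$ratios), function(label) {
    tr <- st$truth$per_comparison[[label]]
    list(up = gene_list(tr$up, label, "up"),
         down = gene_list(tr$down, label, "down"))
  })
  names(gl) <- names(st$ratios)
  cl <- lapply(names(st$ratios), function(label) {
    tr <- st$truth$per_comparison[[label]]
    mapped <- m[!is.na(m$gene_id), ]
    list(up = mapped$clone_id[mapped$gene_id %in% tr$up],
         down = mapped$clone_id[mapped$gene_id %in% tr$down])
  })
  names(cl) <- names(st$ratios)
  vc <- venn_counts(gl, cl, m)
  for (dir in c("down", "up")) {
    got <- setNames(vc$n_genes[vc$direction == dir],
                    vc$region[vc$direction == dir])
    expect_equal(got[names(cfg$planted_sizes[[dir]])],
                 cfg$planted_sizes[[dir]])
  }
})

test_that("direction-conflicted genes are excluded from both lists", {
  mapping <- resolve_best_match(data.frame(
    clone_id = c("c1", "c2", "c3"),
    gene_id = c("gA", "gA", "gB"),
    score = 1, stringsAsFactors = FALSE))
  fake_calls <- structure(list(up_clones = "c1",
                               down_clones = c("c2", "c3")),
                          class = "de_calls")
  expect_message(gl <- directional_gene_lists(fake_calls, mapping, "X"),
                 "direction-conflicted")
  expect_identical(gl$conflicted, "gA")
  expect_length(gl$up, 0)
  expect_identical(as.character(gl$down), "gB")
})
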