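test_that("presence matrix derives families and trypsin associations per taxon", {
  per_taxon <- list(
    Nv = c("Trypsin|ShK", "Trypsin"),
    El = c("Trypsin"))
  pm <- presence_from_architectures(per_taxon)
  expect_true(pm["Trypsin", "Nv"])
  expect_true(pm["trypsin+ShK", "Nv"])
  expect_false(pm["trypsin+ShK", "El"])
  expect_true(pm["Trypsin", "El"])
  # a taxon with only trypsin-only proteins has no association features
  only <- presence_from_architectures(list(T1 = "Trypsin"))
  expect_equal(rownames(only), "Trypsin")
})

test_that("origin assignment equals the brute-force all-nodes oracle", {
  set.seed(21)
  for (rep in 1:40) {
    n <- sample(4:32, 1)
    tree <- ape::rtree(n)
    k <- sample(1:n, 1)
    pres <- sample(tree$tip.label, k)
    pm <- matrix(tree$tip.label %in% pres, nrow = 1,
                 dimnames = list("f", tree$tip.label))
    got <- assign_origin(pm, tree)
    expect_equal(got$origin_node, oracle_origin(tree, pres))
  }
})

test_that("origin stratum, losses and root conventions behave as specified", {
  tree <- ape::read.tree(text = "(((A,B),(C,D)),(E,(F,G)));")
  pm <- rbind(
    leafonly = c(A = TRUE, B = FALSE, C = FALSE, D = FALSE, E = FALSE,
                 F = FALSE, G = FALSE),
    pairAB   = c(A = TRUE, B = TRUE, C = FALSE, D = FALSE, E = FALSE,
                 F = FALSE, G = FALSE),
    straddle = c(A = TRUE, B = FALSE, C = FALSE, D = TRUE, E = FALSE,
                 F = FALSE, G = FALSE),
    rooted   = c(A = TRUE, B = FALSE, C = FALSE, D = FALSE, E = FALSE,
                 F = FALSE, G = TRUE))
  pm <- pm[, tree$tip.label]
  res <- assign_origin(pm, tree)
  # present in one taxon: origin is that leaf, no losses
  leaf <- res[res$feature == "leafonly", ]
  expect_equal(leaf$origin_label, "A")
  expect_equal(leaf$n_losses, 0L)
  # a cherry with both members present: no losses
  expect_equal(res$n_losses[res$feature == "pairAB"], 0L)
  # presence straddling the root of a subtree: losses are the maximal
  # absent clades (B and C), disjoint from presence taxa
  st <- res[res$feature == "straddle", ]
  losses <- st$losses[[1]]
  expect_setequal(unlist(losses), c("B", "C"))
  expect_true(all(!unlist(losses) %in% c("A", "D")))
  # outgroup + ingroup presence dates to the root (stratum 0)
  expect_equal(res$stratum[res$feature == "rooted"], 0L)
  # adding a presence taxon never makes an origin younger
  pm2 <- pm
  pm2["pairAB", "G"] <- TRUE
  res2 <- assign_origin(pm2, tree)
  expect_lte(res2$stratum[res2$feature == "pairAB"],
             res$stratum[res$feature == "pairAB"])
  # zero-presence features are skipped with a warning
  pm3 <- rbind(pm, none = rep(FALSE, 7))
  expect_warning(res3 <- assign_origin(pm3, tree), "no presence")
  expect_false("none" %in% res3$feature)
})

test_that("planted gain nodes are recovered when no losses occur", {
  sim <- sim_presence(n_leaves = 16, n_features = 100, loss_prob = 0,
                      seed = 31)
  res <- assign_origin(sim$presence, sim$tree)
  expect_equal(res$origin_node,
               sim$truth$gain_node[match(res$feature, sim$truth$feature)])
})

test_that("loss clades are maximal and mutually disjoint under simulated loss", {
  sim <- sim_presence(n_leaves = 16, n_features = 60, loss_prob = 0.25,
                      seed = 32)
  res <- assign_origin(sim$presence, sim$tree)
  for (i in seq_len(nrow(res))) {
    sets <- res$losses[[i]]
    if (length(sets) < 2) next
    for (a in seq_along(sets)) for (b in seq_along(sets)) {
      if (a < b) expect_length(intersect(sets[[a]], sets[[b]]), 0)
    }
    pres <- colnames(sim$presence)[sim$presence[res$feature[i], ]]
    expect_length(intersect(unlist(sets), pres), 0)
  }
})

test_that("age relationship computes tie-corrected Spearman and checks ordering", {
  dom <- data.frame(feature = c("X", "Y", "Z", "W"),
                    stratum = c(0L, 1L, 2L, 3L))
  assoc <- data.frame(feature = paste0("trypsin+", c("X", "Y", "Z", "W")),
                      stratum = c(2L, 3L, 4L, 5L))
  res <- age_relationship(dom, assoc)
  expect_equal(res$rho, 1)
  expect_equal(res$n, 4L)
  # brute-force rank computation on a 6-pair table with ties
  dom6 <- data.frame(feature = letters[1:6], stratum = c(0, 0, 1, 2, 2, 3))
  as6 <- data.frame(feature = paste0("trypsin+", letters[1:6]),
                    stratum = c(3, 1, 5, 2, 4, 4))
  res6 <- age_relationship(dom6, as6)
  expect_equal(res6$rho,
               unname(cor(rank(dom6$stratum), rank(as6$stratum))))
  # an association older than its domain is an inconsistency
  bad <- data.frame(feature = "trypsin+X", stratum = 0L)
  expect_error(age_relationship(dom[dom$feature == "X", ],
                                transform(bad, stratum = -1L)),
               "older than its domain")
  expect_error(
    age_relationship(dom, data.frame(feature = "trypsin+missing",
                                     stratum = 5L)),
    "without matching domain")
})

test_that("tree pruning yields the induced subtree", {
  # oracle: the clades of the induced subtree are exactly the distinct
  # nonempty intersections of the original clades with the kept taxa
  clade_strings <- function(tree) {
    nodes <- seq_len(ape::Ntip(tree) + tree$Nnode)
    unique(vapply(nodes, function(nd) {
      paste(sort(tips_of(tree, nd)), collapse = "|")
    }, character(1)))
  }
  set.seed(41)
  for (rep in 1:20) {
    tree <- ape::rtree(sample(5:20, 1))
    keep <- sample(tree$tip.label, sample(2:ape::Ntip(tree), 1))
    pr <- prune_tree(tree, keep)
    expect_setequal(pr$tip.label, keep)
    nodes <- seq_len(ape::Ntip(tree) + tree$Nnode)
    expected <- unique(Filter(nzchar, vapply(nodes, function(nd) {
      paste(sort(intersect(tips_of(tree, nd), keep)), collapse = "|")
    }, character(1))))
    expect_setequal(clade_strings(pr), expected)
  }
  tree <- ape::rtree(8)
  expect_equal(prune_tree(tree, tree$tip.label), tree)
  pr2 <- prune_tree(tree, tree$tip.label[1:2])
  expect_equal(ape::Ntip(pr2), 2L)
  expect_error(prune_tree(tree, "not-a-taxon"), "unknown")
})
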