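# shared fixtures: built once per test run
fixture_aln <- build_study_alignment(study_fixture_spec(seed = 1))
fixture_groups <- study_groups()
fixture_dm <- distance_matrix(fixture_aln, "k2p", "pairwise")

id_st <- fixture_groups$id[fixture_groups$group == "stigmaticum"]
id_br <- fixture_groups$id[fixture_groups$group == "brunneum"]
id_ch <- fixture_groups$id[fixture_groups$group == "chloroticum"]

# a species-level 3-taxon K2P matrix at full precision
species_dm <- local({
  d <- matrix(0, 3, 3, dimnames = list(c("br", "ch", "st"), c("br", "ch", "st")))
  d["st", "br"] <- d["br", "st"] <- unclass(fixture_dm)[id_st[1], id_br[1]]
  d["st", "ch"] <- d["ch", "st"] <- unclass(fixture_dm)[id_st[1], id_ch[1]]
  d["br", "ch"] <- d["ch", "br"] <- unclass(fixture_dm)[id_br[1], id_ch[1]]
  d
})

# random ultrametric-free additive distance matrix from a random topology;
# returns list(tree, dm) with the tree's path-length matrix as dm
random_additive_case <- function(n_tips) {
  tree <- ape::rtree(n_tips, br = function(k) runif(k, 0.05, 1))
  tree <- ape::unroot(tree)
  dm <- cophenetic(tree)
  ord <- sort(rownames(dm))
  list(tree = tree, dm = dm[ord, ord])
}

# unordered-bipartition comparison of two unrooted trees
same_topology <- function(t1, t2) {
  identical(sort(aylacostoma:::tree_splits(t1)),
            sort(aylacostoma:::tree_splits(t2)))
}
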