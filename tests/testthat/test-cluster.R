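base20 <- "MKTLISAGCDEFHNPQRVWY"

test_that("enumerate_candidates merges evidence streams and annotates", {
  bv <- parse_variant_name("", base20)
  pssm_subs <- data.frame(position = c(2L, 5L, 7L), from = c("K", "I", "A"),
                          to = c("R", "V", "G"), score = c(1.5, 2.0, 0.7))
  coev_subs <- data.frame(position = c(5L, 9L), from = c("I", "C"),
                          to = c("V", "S"), partner_position = c(11L, 3L),
                          coupling_gain = c(0.9, 0.4))
  env <- data.frame(residue_number = c(2L, 5L, 7L, 9L),
                    chain = "A", resname = "ALA",
                    rsa = c(0.6, 0.3, 0.02, 0.1),
                    burial_class = c("surface", "surface", "buried",
                                     "semi-exposed"),
                    pocket = c(FALSE, FALSE, TRUE, FALSE),
                    min_ligand_distance = c(20, 15, 3, 8))
  vs <- enumerate_candidates(bv, pssm_subs, coev_subs, env)
  expect_equal(length(vs$variants), 4L)  # I5V proposed twice, merged
  i5v <- vs$table[vs$table$name == "I5V", ]
  expect_equal(i5v$provenance, "coevolution,pssm")
  expect_equal(i5v$score, -(2.0) - (0.9))
  expect_equal(vs$table$score[vs$table$name == "K2R"], -1.5)
  expect_equal(vs$table$burial_class[vs$table$name == "A7G"], "buried")

  surf <- enumerate_candidates(bv, pssm_subs, coev_subs, env,
                               filter = "surface")
  expect_equal(sort(surf$table$name), c("I5V", "K2R"))
  pock <- enumerate_candidates(bv, pssm_subs, coev_subs, env,
                               filter = "pocket")
  expect_equal(pock$table$name, "A7G")

  # missing environment entry -> class unknown with warning
  expect_warning(
    vs2 <- enumerate_candidates(bv, pssm_subs, coev_subs, env[-4, ]),
    "unknown")
  expect_equal(vs2$table$burial_class[vs2$table$name == "C9S"], "unknown")
})

base_i46 <- function(b) {
  # widen the 20-mer to 50 residues with an I at 46
  ch <- strsplit(paste(rep(b, 3), collapse = ""), "")[[1]][1:50]
  ch[46] <- "I"
  paste(ch, collapse = "")
}

test_that("variant_distance matches direct PAM30 lookups", {
  pam <- pam30_matrix()
  a <- parse_variant_name("I46L", base_i46(base20))
  b <- parse_variant_name("", base_i46(base20))
  d <- variant_distance(a, b, pam)
  expect_equal(d, (pam["I", "I"] + pam["L", "L"] - 2 * pam["I", "L"]) / 2)
  expect_equal(variant_distance(a, a, pam), 0)
  expect_equal(variant_distance(b, b, pam), 0)
})

test_that("variant distances are symmetric with zero self-distance", {
  set.seed(41)
  base <- paste(sample(aa_alphabet(), 60, TRUE), collapse = "")
  for (rep in 1:10) {
    va <- parse_variant_name(random_variant(base, 3)$name, base)
    vb <- parse_variant_name(random_variant(base, 2)$name, base)
    expect_equal(variant_distance(va, vb), variant_distance(vb, va))
    expect_gte(variant_distance(va, vb), 0)
    expect_equal(variant_distance(va, va), 0)
  }
  other <- parse_variant_name("", paste(rev(strsplit(base, "")[[1]]),
                                        collapse = ""))
  expect_error(variant_distance(parse_variant_name("", base), other),
               "different base")
})

test_that("cluster_variants recovers well-separated groups", {
  base <- paste(rep("A", 30), collapse = "")
  # two triplets around distinct substitutions; within-group distances are
  # small, between-group large
  nm <- c("A1C-A2C", "A1C-A2C-A3S", "A1C-A2C-A4S",
          "A20W-A21W", "A20W-A21W-A22S", "A20W-A21W-A23S")
  vs <- variant_set_from(base, nm)
  ca <- cluster_variants(vs, k = 2)
  expect_equal(ca$labels[1:3], rep(ca$labels[1], 3))
  expect_equal(ca$labels[4:6], rep(ca$labels[4], 3))
  expect_false(ca$labels[1] == ca$labels[4])

  # k = n gives singletons; k out of range errors
  expect_equal(sort(cluster_variants(vs, k = 6)$labels), 1:6)
  expect_error(cluster_variants(vs, k = 0), "between")
  expect_error(cluster_variants(vs, k = 7), "between")
})

test_that("average-linkage labels agree with hclust on tie-free fixtures", {
  set.seed(55)
  base <- paste(sample(aa_alphabet(), 40, TRUE), collapse = "")
  for (rep in 1:5) {
    nm <- vapply(1:7, function(i) random_variant(base, 2)$name, character(1))
    vs <- variant_set_from(base, unique(nm))
    n <- length(vs$variants)
    if (n < 4) next
    D <- variant_distance_matrix(vs)
    # jitter to remove ties so linkage order is unambiguous
    J <- matrix(0, n, n)
    J[upper.tri(J)] <- runif(n * (n - 1) / 2, 0, 1e-6)
    D <- D + J + t(J)
    for (k in 2:(n - 1)) {
      got <- cluster_variants(vs, k = k, distance = D)$labels
      ref <- stats::cutree(stats::hclust(stats::as.dist(D),
                                         method = "average"), k = k)
      # compare partitions up to label renaming
      expect_equal(length(unique(got)), k)
      agree <- outer(got, got, "==") == outer(ref, ref, "==")
      expect_true(all(agree))
    }
  }
})

test_that("clustering is invariant to variant order", {
  set.seed(66)
  base <- paste(sample(aa_alphabet(), 40, TRUE), collapse = "")
  nm <- unique(vapply(1:8, function(i) random_variant(base, 2)$name,
                      character(1)))
  vs <- variant_set_from(base, nm, scores = seq_along(nm))
  ca <- cluster_variants(vs, k = 3)
  perm <- sample(length(nm))
  vsp <- variant_set_from(base, nm[perm], scores = seq_along(nm)[perm])
  cap <- cluster_variants(vsp, k = 3)
  same_part <- outer(ca$labels, ca$labels, "==")
  same_perm <- outer(cap$labels, cap$labels, "==")[order(perm), order(perm)]
  expect_equal(same_part, same_perm)
})

test_that("select_representatives picks the lowest score, ties by name", {
  base <- paste(rep("A", 30), collapse = "")
  nm <- c("A1C", "A2C", "A3C", "A20W", "A21W")
  vs <- variant_set_from(base, nm, scores = c(-3, -1, 0, -2, -2))
  # explicit block-structured distances: {1,2,3} vs {4,5}
  D <- matrix(10, 5, 5)
  D[1:3, 1:3] <- 1; D[4:5, 4:5] <- 1
  diag(D) <- 0
  ca <- cluster_variants(vs, k = 2, distance = D)
  reps <- select_representatives(ca)
  expect_equal(length(reps), 2L)
  rep_names <- sort(vapply(reps, `[[`, character(1), "name"))
  expect_equal(rep_names, c("A1C", "A20W"))  # -3 wins; tie -2/-2 by name
  # representatives' scores are minimal within their cluster
  for (r in reps) {
    cl <- ca$labels[vapply(ca$variants, `[[`, character(1), "name") == r$name]
    in_cl <- vapply(ca$variants[ca$labels == cl], `[[`, numeric(1), "score")
    expect_true(all(r$score <= in_cl))
  }
})

test_that("write_variant_report includes clusters and representative flags", {
  base <- paste(rep("A", 10), collapse = "")
  bv <- parse_variant_name("", base)
  pssm_subs <- data.frame(position = 1:4, from = "A",
                          to = c("C", "D", "W", "Y"),
                          score = c(1, 2, 0.5, 0.1))
  vs <- enumerate_candidates(bv, pssm_subs, NULL, NULL)
  ca <- cluster_variants(vs, k = 2)
  p <- tempfile(fileext = ".tsv")
  df <- write_variant_report(vs, ca, p)
  tab <- read.delim(p)
  expect_equal(nrow(tab), 4L)
  expect_equal(sum(tab$representative), 2L)
  expect_true(all(c("name", "provenance", "burial_class", "pocket", "score",
                    "cluster", "representative") %in% names(tab)))
})
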