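test_that("classical MDS handles degenerate and symmetric cases", {
  lab3 <- paste0("P", 1:3)
  zero <- matrix(0, 3, 3, dimnames = list(lab3, lab3))
  m0 <- suppressWarnings(classical_mds(zero, dims = 2))
  expect_true(all(m0$coordinates == 0))
  # three equidistant populations: eigenvalues (0.5, 0.5, 0) and unit
  # recovered distances
  ones <- matrix(1, 3, 3, dimnames = list(lab3, lab3)); diag(ones) <- 0
  m1 <- classical_mds(ones, dims = 2)
  expect_equal(m1$eigenvalues, c(0.5, 0.5, 0), tolerance = 1e-10)
  expect_equal(as.vector(dist(m1$coordinates)), rep(1, 3), tolerance = 1e-10)
  # coordinates column-centered
  expect_equal(colSums(m1$coordinates), c(dim1 = 0, dim2 = 0), tolerance = 1e-10)
  # requesting too many dims reduces with a warning
  expect_warning(mr <- classical_mds(ones, dims = 3), "reducing dims")
  expect_equal(mr$dims, 2)
  expect_error(classical_mds(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("MDS reproduces distances from planar configurations", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(4:10, 1)
    pts <- matrix(rnorm(2 * n), n, 2)
    D <- as.matrix(dist(pts))
    dimnames(D) <- list(paste0("P", 1:n), paste0("P", 1:n))
    m <- classical_mds(D, dims = 2)
    expect_equal(as.vector(dist(m$coordinates)), as.vector(dist(pts)),
                 tolerance = 1e-8)
    expect_equal(m$goodness, 1, tolerance = 1e-8)
    # agreement with the independent implementation in stats::cmdscale
    ref <- stats::cmdscale(D, k = 2)
    expect_equal(as.vector(dist(m$coordinates)), as.vector(dist(ref)),
                 tolerance = 1e-8)
  }
})

test_that("MDS output is stable under permutation of population order", {
  set.seed(10)
  pts <- matrix(rnorm(12), 6, 2)
  D <- as.matrix(dist(pts))
  dimnames(D) <- list(paste0("P", 1:6), paste0("P", 1:6))
  perm <- sample(6)
  m1 <- classical_mds(D, 2)
  m2 <- classical_mds(D[perm, perm], 2)
  d1 <- as.matrix(dist(m1$coordinates))
  d2 <- as.matrix(dist(m2$coordinates))[rownames(D), rownames(D)]
  expect_equal(d1, d2, tolerance = 1e-8)
})

test_that("neighbor joining reproduces the worked additive example", {
  lab <- LETTERS[1:4]
  D <- matrix(c(0, 5, 7, 8, 5, 0, 8, 9, 7, 8, 0, 9, 8, 9, 9, 0), 4, 4,
              dimnames = list(lab, lab))
  tr <- neighbor_joining(D)
  # topology (A,B | C,D), leaf branches 2,3,4,5, internal edge 1
  ct <- ape::cophenetic.phylo(tr)[lab, lab]
  expect_equal(ct, D, tolerance = 1e-9)
  leaf_edges <- tr$edge.length[tr$edge[, 2] <= 4]
  expect_equal(sort(leaf_edges), c(2, 3, 4, 5), tolerance = 1e-9)
  internal <- tr$edge.length[tr$edge[, 2] > 4]
  expect_equal(internal, 1, tolerance = 1e-9)
})

test_that("three- and two-taxon trees use the closed forms", {
  lab <- c("A", "B", "C")
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3, dimnames = list(lab, lab))
  tr <- neighbor_joining(D)
  bl <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(bl[["A"]], (3 + 4 - 5) / 2)
  expect_equal(bl[["B"]], (3 + 5 - 4) / 2)
  expect_equal(bl[["C"]], (4 + 5 - 3) / 2)
  # two taxa: degenerate single-edge tree, total path d(1,2)
  D2 <- matrix(c(0, 0.8, 0.8, 0), 2, 2,
               dimnames = list(c("P1", "P2"), c("P1", "P2")))
  t2 <- neighbor_joining(D2)
  expect_equal(sum(t2$edge.length), 0.8)
})

test_that("equidistant taxa give a zero internal edge via the stated tie rule", {
  lab <- LETTERS[1:4]
  D <- matrix(2, 4, 4, dimnames = list(lab, lab)); diag(D) <- 0
  tr <- neighbor_joining(D)
  leaf_edges <- tr$edge.length[tr$edge[, 2] <= 4]
  expect_equal(leaf_edges, rep(1, 4), tolerance = 1e-12)
  expect_equal(tr$edge.length[tr$edge[, 2] > 4], 0, tolerance = 1e-12)
  # the tie broke on the lowest index pair: A and B are sisters
  pairs <- ape::prop.part(ape::unroot(tr))
  expect_true(any(vapply(pairs, function(p) setequal(lab[p], c("A", "B")) ||
                           setequal(lab[p], c("C", "D")), logical(1))))
})

test_that("NJ is exact on random additive matrices of 4-12 leaves", {
  for (seed in 1:8) {
    n <- sample(4:12, 1)
    fix <- random_additive_tree(n, seed = 400 + seed)
    tr <- neighbor_joining(fix$D)
    # path lengths between all leaves match the generating tree exactly
    ct <- ape::cophenetic.phylo(tr)[rownames(fix$D), colnames(fix$D)]
    expect_equal(ct, fix$D, tolerance = 1e-9)
    # identical unrooted topology (Robinson-Foulds distance 0)
    expect_equal(phangorn::RF.dist(ape::unroot(tr), ape::unroot(fix$tree)), 0)
    # and agreement with the independent ape implementation
    expect_equal(phangorn::RF.dist(ape::unroot(tr),
                                   ape::unroot(ape::nj(fix$D))), 0)
  }
})
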