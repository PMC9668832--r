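# Structure utilities: N-H vectors, C2 alignment, B-factor value maps.

test_that("toy dimer is exactly C2-symmetric with unit paired vectors", {
  toy <- make_toy_dimer(10)
  A <- toy$atoms[toy$atoms$chain == "A", ]
  B <- toy$atoms[toy$atoms$chain == "B", ]
  expect_equal(B$x, -A$x)
  expect_equal(B$y, -A$y)
  expect_equal(B$z, A$z)
  nrm <- sqrt(rowSums(toy$nh_vectors^2))
  expect_true(all(abs(nrm - 1) < 1e-9))
  for (i in 2:10) {
    vA <- toy$nh_vectors[paste0("A:", i), ]
    vB <- toy$nh_vectors[paste0("B:", i), ]
    expect_equal(unname(vB), unname(c(-vA[1], -vA[2], vA[3])))
  }
})

test_that("N-H vectors match hand geometry and ignore atom order", {
  atoms <- data.frame(
    chain = "A", resno = c(1, 1, 1, 2, 2, 2, 2),
    resid = "ALA",
    elety = c("N", "CA", "C", "N", "H", "CA", "C"),
    x = c(0, 1.4, 2.0, 3.3, 3.3, 4.2, 5.4),
    y = c(0, 0.3, 1.5, 1.6, 2.62, 2.4, 2.0),
    z = 0, b = 0, o = 1)
  nh <- nh_vectors(atoms)
  expect_equal(unname(nh$vectors["A:2", ]), c(0, 1, 0))
  # chain start has no preceding carbonyl and no H: reported, not faked
  expect_true("A:1" %in% nh$skipped$residue_id)
  # atom order within residues is immaterial
  nh2 <- nh_vectors(atoms[sample(nrow(atoms)), ])
  expect_equal(nh2$vectors, nh$vectors)
})

test_that("constructed amide H reproduces a stripped explicit H direction", {
  toy <- make_toy_dimer(8)
  with_h <- nh_vectors(toy$atoms)$vectors
  no_h <- nh_vectors(toy$atoms[toy$atoms$elety != "H", ])$vectors
  ids <- intersect(rownames(with_h), rownames(no_h))
  ang <- acos(pmin(rowSums(with_h[ids, ] * no_h[ids, ]), 1)) * 180 / pi
  expect_true(all(ang < 5))
})

test_that("prolines are skipped with a report", {
  toy <- make_toy_dimer(5)
  at <- toy$atoms
  at$resid[at$chain == "A" & at$resno == 3] <- "PRO"
  nh <- nh_vectors(at)
  expect_true("A:3" %in% nh$skipped$residue_id)
  expect_false("A:3" %in% rownames(nh$vectors))
})

test_that("alignment of an already C2-aligned dimer is the identity", {
  toy <- make_toy_dimer(10)
  al <- align_c2(toy)
  rep <- attr(al, "c2_report")
  expect_equal(rep$angle_deg, 180, tolerance = 1e-6)
  expect_lt(rep$rmsd, 1e-9)
  expect_lt(max(abs(al$atoms$x - toy$atoms$x)), 1e-9)
})

test_that("a planted rigid rotation is recovered to within 0.1 degree", {
  toy <- make_toy_dimer(10)
  set.seed(33)
  for (i in 1:3) {
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
    th <- runif(1, 0.2, 2.5)
    K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
                3, 3, byrow = TRUE)
    R0 <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
    at <- toy$atoms
    xyz <- as.matrix(at[, c("x", "y", "z")]) %*% t(R0)
    at$x <- xyz[, 1] + 3; at$y <- xyz[, 2] - 5; at$z <- xyz[, 3] + 1
    al <- align_c2(structure_frame(at))
    # after alignment the symmetry axis must be z again
    rep2 <- attr(align_c2(al), "c2_report")
    dev <- acos(min(abs(rep2$axis[3]), 1)) * 180 / pi
    expect_lt(dev, 0.1)
  }
})

test_that("swapping chain roles yields the same canonical axis", {
  toy <- make_toy_dimer(8)
  a1 <- attr(align_c2(toy, c("A", "B")), "c2_report")$axis
  a2 <- attr(align_c2(toy, c("B", "A")), "c2_report")$axis
  expect_equal(a1, a2, tolerance = 1e-9)
  expect_gte(a1[3], 0)
})

test_that("alignment preserves all intra-chain distances", {
  toy <- make_toy_dimer(8)
  at <- toy$atoms
  xyz <- as.matrix(at[, c("x", "y", "z")])
  R0 <- relaxmf:::rotation_to_z(c(1, 2, 2) / 3)
  xyz2 <- xyz %*% t(R0)
  at$x <- xyz2[, 1]; at$y <- xyz2[, 2]; at$z <- xyz2[, 3]
  al <- align_c2(structure_frame(at))
  A0 <- xyz2[at$chain == "A", ][1:15, ]
  A1 <- as.matrix(al$atoms[al$atoms$chain == "A", c("x", "y", "z")])[1:15, ]
  expect_equal(as.vector(dist(A1)), as.vector(dist(A0)),
               tolerance = 1e-9)
})

test_that("a non-C2 pair is refused unless forced", {
  toy <- make_toy_dimer(8)
  at <- toy$atoms
  # rotate chain B by an extra 60 degrees: no longer a two-fold
  bidx <- at$chain == "B"
  th <- 60 * pi / 180
  xb <- at$x[bidx] * cos(th) - at$y[bidx] * sin(th)
  yb <- at$x[bidx] * sin(th) + at$y[bidx] * cos(th)
  at$x[bidx] <- xb; at$y[bidx] <- yb
  expect_error(align_c2(structure_frame(at)), "not C2-symmetric")
  expect_s3_class(align_c2(structure_frame(at), force = TRUE),
                  "structure_frame")
})

test_that("value maps scale into the B column with a lossless sidecar", {
  toy <- make_toy_dimer(5)
  ids <- paste0("A:", 1:3)
  f <- tempfile(fileext = ".pdb")
  write_value_map(toy, setNames(c(0, 50, 100), ids), f, kind = "Rex")
  pdb <- read_structure(f)
  b <- tapply(pdb$atoms$b, paste0(pdb$atoms$chain, ":", pdb$atoms$resno),
              unique)
  expect_equal(as.numeric(b[ids]), c(0, 50, 99.99))
  expect_equal(as.numeric(b[["B:1"]]), 0)   # unmapped residues get 0.00
  side <- read.table(paste0(f, ".values.tsv"), header = TRUE, sep = "\t",
                     comment.char = "#")
  expect_equal(side$value[match(ids, side$residue_id)], c(0, 50, 100))
  # constant map -> constant B column
  f2 <- tempfile(fileext = ".pdb")
  write_value_map(toy, setNames(c(5, 5, 5), ids), f2, kind = "S2")
  pdb2 <- read_structure(f2)
  expect_equal(length(unique(pdb2$atoms$b)), 1)
  expect_error(write_value_map(toy, setNames(1, "A:1"), f2),
               "kind")
})

test_that("structure read/write round trip preserves coordinates", {
  toy <- make_toy_dimer(6)
  f <- tempfile(fileext = ".pdb")
  write_structure(toy, f)
  rt <- read_structure(f)
  expect_equal(rt$atoms$x, round(toy$atoms$x, 3))
  expect_equal(rt$atoms$y, round(toy$atoms$y, 3))
  expect_equal(rt$atoms$z, round(toy$atoms$z, 3))
  expect_equal(rt$atoms$elety, toy$atoms$elety)
  expect_equal(rt$atoms$chain, toy$atoms$chain)
})
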