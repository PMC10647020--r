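hexagon_xyz <- cbind(1.39 * cos(2 * pi * (0:5) / 6),
                     1.39 * sin(2 * pi * (0:5) / 6), 0)

feat_df <- function(types, xyz) {
  data.frame(type = types, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             owner = I(as.list(seq_along(types))))
}

test_that("benzene yields exactly one aromatic feature at the centroid", {
  benz <- mol_graph(rep("C", 6), data.frame(i = 1:6, j = c(2:6, 1), order = 4))
  f <- detect_features(benz, conformer(hexagon_xyz))
  expect_equal(nrow(f), 1L)
  expect_equal(f$type, "Aromatic")
  expect_lt(max(abs(c(f$x, f$y, f$z))), 1e-6)  # centroid of symmetric ring
})

test_that("hydroxyl oxygen is both donor and acceptor at the O position", {
  eth <- mol_graph(c("C", "C", "O"), data.frame(i = 1:2, j = 2:3, order = 1))
  xyz <- matrix(c(0, 0, 0, 1.54, 0, 0, 2.05, 1.45, 0), 3, 3, byrow = TRUE)
  f <- detect_features(eth, conformer(xyz))
  expect_setequal(f$type, c("HydrogenDonor", "HydrogenAcceptor"))
  expect_true(all(abs(f$x - 2.05) < 1e-9 & abs(f$y - 1.45) < 1e-9))
})

test_that("methane has no polar features; alkanes gain hydrophobic centroids", {
  f <- detect_features(mol_graph("C", NULL), conformer(matrix(0, 1, 3)))
  expect_equal(nrow(f), 0L)
  prop <- mol_graph(rep("C", 3), data.frame(i = 1:2, j = 2:3, order = 1))
  xyz <- matrix(c(0, 0, 0, 1, 0, 0, 2, 0, 0), 3, 3, byrow = TRUE)
  fp <- detect_features(prop, conformer(xyz))
  expect_equal(fp$type, "Hydrophobic")
  expect_equal(fp$x, 1)
})

test_that("charged atoms give ionic features, not donors or acceptors", {
  m <- mol_graph(c("C", "N", "C", "O"),
                 data.frame(i = c(1, 2, 3), j = c(2, 3, 4), order = 1),
                 charges = c(0L, 1L, 0L, -1L))
  f <- detect_features(m, conformer(matrix(rnorm(12), 4, 3)))
  expect_setequal(f$type, c("PositiveIon", "NegativeIon"))
})

test_that("amide and aniline-type nitrogens are excluded from acceptors", {
  # acetamide N: N-C(=O)
  amide <- mol_graph(c("N", "C", "O", "C"),
                     data.frame(i = c(1, 2, 2), j = c(2, 3, 4),
                                order = c(1, 2, 1)))
  f <- detect_features(amide, conformer(matrix(rnorm(12), 4, 3)))
  expect_false(any(f$type == "HydrogenAcceptor" &
                     vapply(f$owner, function(o) 1 %in% o, logical(1))))
  expect_true(any(f$type == "HydrogenDonor"))  # the NH2 still donates
})

test_that("complementary pairs within cutoff are detected, others not", {
  lig <- feat_df("HydrogenDonor", matrix(c(0, 0, 0), 1))
  rec3 <- feat_df("HydrogenAcceptor", matrix(c(3, 0, 0), 1))
  p <- detect_interactions(lig, rec3)
  expect_equal(nrow(p$entries), 1L)
  expect_equal(p$entries$distance, 3)
  # same pair beyond the 4 A donor-acceptor cutoff
  rec5 <- feat_df("HydrogenAcceptor", matrix(c(5, 0, 0), 1))
  expect_equal(nrow(detect_interactions(lig, rec5)$entries), 0L)
  # non-complementary donor vs donor, even when close
  recd <- feat_df("HydrogenDonor", matrix(c(2.5, 0, 0), 1))
  expect_equal(nrow(detect_interactions(lig, recd)$entries), 0L)
})

test_that("query enumeration counts follow the binomial sums", {
  pts <- matrix(c(0, 0, 0, 4, 0, 0, 0, 4, 0, 4, 4, 0, 2, 2, 5), 5, 3,
                byrow = TRUE)
  lig <- feat_df(rep("HydrogenDonor", 5), pts)
  rec <- feat_df(rep("HydrogenAcceptor", 5), pts + 1)
  profile <- detect_interactions(lig, rec)
  expect_equal(length(enumerate_queries(profile)), 16L)      # C(5,3)+C(5,4)+C(5,5)
  expect_equal(length(enumerate_queries(profile, 3, 3)), 10L) # C(5,3)
  lig3 <- feat_df(rep("HydrogenDonor", 3), pts[1:3, ])
  rec3 <- feat_df(rep("HydrogenAcceptor", 3), pts[1:3, ] + 1)
  expect_equal(length(enumerate_queries(detect_interactions(lig3, rec3))), 1L)
  # pool below the minimum: empty with a notice
  expect_message(
    qs <- enumerate_queries(detect_interactions(lig3, rec3), min_features = 8),
    "smaller than min_features")
  expect_length(qs, 0L)
})

test_that("enumerated query counts always satisfy the subset formula", {
  withr::with_seed(5, {
    for (pool in 3:7) {
      pts <- matrix(runif(pool * 3, 0, 10), pool, 3)
      lig <- feat_df(rep("Hydrophobic", pool), pts)
      rec <- feat_df(rep("Hydrophobic", pool), pts + 0.5)
      profile <- detect_interactions(lig, rec)
      for (mn in 3:pool) {
        got <- length(enumerate_queries(profile, min_features = mn))
        expect_equal(got, sum(choose(pool, mn:pool)))
      }
    }
  })
})

test_that("exact geometry matches and far geometry does not", {
  withr::with_seed(9, {
    pts <- matrix(runif(12, 0, 8), 4, 3)
    types <- c("HydrogenDonor", "HydrogenAcceptor", "PositiveIon",
               "Hydrophobic")
    q <- pharm_query(feat_df(types, pts), tolerance = 1.0)
    # identical copy, arbitrarily rotated/translated
    moved <- rigid_transform(pts)
    expect_true(isTRUE(match_query(q, feat_df(types, moved))))
    m <- match_query(q, feat_df(types, moved))
    expect_s3_class(attr(m, "witness"), "data.frame")
    # one feature displaced far beyond feasibility
    broken <- pts; broken[2, ] <- broken[2, ] + c(25, 0, 0)
    expect_false(isTRUE(match_query(q, feat_df(types, broken))))
    # missing feature type
    expect_false(isTRUE(match_query(q, feat_df(types[-1], pts[-1, ]))))
  })
})

test_that("match is monotone in tolerance and rigid-invariant", {
  withr::with_seed(17, {
    for (trial in 1:20) {
      pts <- matrix(runif(9, 0, 6), 3, 3)
      types <- sample(feature_types(), 3, replace = TRUE)
      fpts <- matrix(runif(15, 0, 6), 5, 3)
      ftypes <- c(types, sample(feature_types(), 2, replace = TRUE))
      feats <- feat_df(ftypes, rbind(pts + rnorm(9, sd = 0.5), fpts[4:5, ]))
      q_tight <- pharm_query(feat_df(types, pts), tolerance = 0.6)
      q_loose <- pharm_query(feat_df(types, pts), tolerance = 1.4)
      m_tight <- isTRUE(match_query(q_tight, feats))
      m_loose <- isTRUE(match_query(q_loose, feats))
      if (m_tight) expect_true(m_loose)
      # rigid transform of the conformer features changes nothing
      moved <- feats
      moved[, c("x", "y", "z")] <- rigid_transform(feature_coords(feats))
      expect_equal(isTRUE(match_query(q_tight, moved)), m_tight)
      expect_equal(isTRUE(match_query(q_loose, moved)), m_loose)
    }
  })
})

test_that("matcher agrees with the exhaustive correspondence oracle", {
  withr::with_seed(23, {
    agree <- 0L; n_trials <- 120L
    for (trial in seq_len(n_trials)) {
      k <- sample(3:5, 1)
      qpts <- matrix(runif(3 * k, 0, 7), k, 3)
      qtypes <- sample(feature_types()[1:4], k, replace = TRUE)
      q <- pharm_query(feat_df(qtypes, qpts), tolerance = 1.0)
      nf <- sample(k:(k + 3), 1)
      if (runif(1) < 0.5) {
        fpts <- rbind(rigid_transform(qpts) +
                        matrix(rnorm(3 * k, sd = 0.25), k, 3),
                      matrix(runif(3 * (nf - k), 0, 7), nf - k, 3))
        ftypes <- c(qtypes, sample(feature_types()[1:4], nf - k,
                                   replace = TRUE))
      } else {
        fpts <- matrix(runif(3 * nf, 0, 7), nf, 3)
        ftypes <- sample(feature_types()[1:4], nf, replace = TRUE)
      }
      feats <- feat_df(ftypes, fpts)
      if (isTRUE(match_query(q, feats)) == brute_match(q, feats))
        agree <- agree + 1L
    }
    expect_gte(agree / n_trials, 0.99)
  })
})

test_that("library screening uses the any-conformer rule and labels", {
  lib <- make_screening_library(planted_library_spec(
    n_actives = 5, n_decoys = 10, n_features = 3, n_conf = 3, seed = 77))
  flags <- screen_library(list(lib$query), lib$library)
  labels <- attr(flags, "labels")
  expect_true(all(flags[1, labels]))     # every active matches
  expect_false(any(flags[1, !labels]))   # no decoy matches
  # strip the planted conformer from one active: its flag flips off
  a1 <- lib$library[[1]]
  keep <- setdiff(seq_len(length(a1$ensemble)),
                  lib$planted$conformer_index[1])
  lib2 <- lib$library
  lib2[[1]]$ensemble <- a1$ensemble[keep]
  flags2 <- screen_library(list(lib$query), lib2)
  expect_false(flags2[1, 1])
  # and adding it back turns the match on again (any-conformer rule)
  lib2[[1]]$ensemble <- a1$ensemble
  expect_true(screen_library(list(lib$query), lib2)[1, 1])
})

test_that("queries larger than any feature set and empty ensembles miss", {
  lib <- make_screening_library(planted_library_spec(
    n_actives = 2, n_decoys = 2, n_features = 3, n_conf = 2, seed = 3))
  big_q <- pharm_query(feat_df(rep("Aromatic", 7),
                               matrix(runif(21, 0, 9), 7, 3)),
                       tolerance = 1.0)
  flags <- screen_library(list(big_q), lib$library)
  expect_false(any(flags))
  lib_empty <- lib$library
  lib_empty[[1]]$ensemble <- conf_ensemble(lib_empty[[1]]$ensemble$molecule)
  expect_message(flags2 <- screen_library(list(lib$query), lib_empty),
                 "empty ensembles")
  expect_false(flags2[1, 1])
  expect_equal(attr(flags2, "empty"), 1L)
})

test_that("feature JSON round-trips through the Pharmit point schema", {
  withr::with_seed(2, {
    f <- feat_df(c("HydrogenDonor", "Aromatic", "NegativeIon"),
                 matrix(runif(9, -5, 5), 3, 3))
    tmp <- withr::local_tempfile(fileext = ".json")
    write_features_json(f, tmp, radius = 1.25)
    back <- read_features_json(tmp)
    expect_equal(back$type, f$type)
    expect_equal(back$x, f$x, tolerance = 1e-12)
    expect_equal(back$radius, rep(1.25, 3))
    js <- jsonlite::read_json(tmp)
    expect_named(js, "points")
    expect_named(js$points[[1]], c("name", "x", "y", "z", "radius"))
  })
})
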