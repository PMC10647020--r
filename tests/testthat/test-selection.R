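# small ensemble builder with prescribed energies on a fixed chain
chain_fix <- make_torsion_chain(torsion_chain_spec(3, seed = 1))
ens_with_energies <- function(energies, seed = 4) {
  ens <- make_ensemble(chain_fix, length(energies), mixing_weight = 0.3,
                       seed = seed)
  for (k in seq_along(energies)) ens$conformers[[k]]$energy <- energies[k]
  ens
}

test_that("policy constructor validates kind-specific fields", {
  expect_error(selection_policy("lowest_energy", 0), "max_n")
  expect_error(selection_policy("energy_rmsd_filtered", 5), "rmsd_threshold")
  expect_error(selection_policy("lowest_energy", 5, rmsd_threshold = 1),
               "only applies")
  expect_error(selection_policy("unbiased", 5), "seed")
  expect_error(selection_policy("lowest_energy", 5, seed = 1), "only applies")
  expect_s3_class(selection_policy("unbiased", 5, seed = 1),
                  "selection_policy")
})

test_that("unbiased selection is a deterministic order-preserving sample", {
  ens <- ens_with_energies(rnorm(20))
  s1 <- select_unbiased(ens, 7, seed = 99)
  s2 <- select_unbiased(ens, 7, seed = 99)
  expect_equal(length(s1), 7L)
  idx1 <- vapply(s1$conformers, function(cf) cf$provenance$sample, integer(1))
  idx2 <- vapply(s2$conformers, function(cf) cf$provenance$sample, integer(1))
  expect_identical(idx1, idx2)
  expect_identical(idx1, sort(idx1))  # original order preserved
  expect_equal(length(select_unbiased(ens, 50, seed = 1)), 20L)
  expect_error(select_unbiased(conf_ensemble(chain_fix$mol), 3, seed = 1),
               "empty")
})

test_that("unbiased sampling is uniform over conformers", {
  ens <- ens_with_energies(rnorm(250))
  counts <- integer(250)
  for (s in 1:10000) {
    sel <- select_unbiased(ens, 25, seed = s)
    idx <- vapply(sel$conformers, function(cf) cf$provenance$sample,
                  integer(1))
    counts[idx] <- counts[idx] + 1L
  }
  freq <- counts / 10000
  expect_true(all(abs(freq - 0.1) <= 0.01))
})

test_that("lowest-energy selection sorts and breaks ties by index", {
  ens <- ens_with_energies(c(3.2, 1.1, 2.0))
  sel <- select_lowest_energy(ens, 2)
  idx <- vapply(sel$conformers, function(cf) cf$provenance$sample, integer(1))
  expect_equal(idx, c(2L, 3L))
  # all equal -> first max_n by original index
  ens_eq <- ens_with_energies(rep(1.0, 6))
  idx_eq <- vapply(select_lowest_energy(ens_eq, 3)$conformers,
                   function(cf) cf$provenance$sample, integer(1))
  expect_equal(idx_eq, 1:3)
  # max_n = 1 -> global minimum
  ens2 <- ens_with_energies(c(5, -2, 7, 0))
  expect_equal(select_lowest_energy(ens2, 1)$conformers[[1]]$energy, -2)
})

test_that("missing energies are refused with the offending index", {
  ens <- ens_with_energies(c(1, 2, 3))
  ens$conformers[[2]]$energy <- NA_real_
  expect_error(select_lowest_energy(ens, 2), "2")
  expect_error(select_energy_rmsd_filtered(ens, 2, 1.0), "2")
})

test_that("the quoted greedy rule is traced exactly on a hand case", {
  # energies A=1 B=2 C=3; rmsd(B,A) small, rmsd(C,A) and rmsd(C,B) large
  spec <- torsion_chain_spec(2, seed = 8)
  ch <- make_torsion_chain(spec)
  a <- chain_coords(c(-180, -180))
  b <- a + withr::with_seed(15, matrix(rnorm(length(a), sd = 0.02),
                                       nrow(a), 3))  # ~0.02 A from A
  cc <- chain_coords(c(60, 60))            # far from both
  ens <- conf_ensemble(ch$mol, list(
    conformer(a, energy = 1), conformer(b, energy = 2),
    conformer(cc, energy = 3)))
  sel <- select_energy_rmsd_filtered(ens, 2, threshold = 1.0)
  expect_equal(vapply(sel$conformers, function(cf) cf$energy, numeric(1)),
               c(1, 3))
})

test_that("filter that never fires reduces to lowest-energy selection", {
  ens <- make_ensemble(chain_fix, 12, mixing_weight = 0.2,
                       noise_sigma = 0.05, seed = 21)
  # jitter makes all conformers distinct; tiny threshold never rejects
  sel_f <- select_energy_rmsd_filtered(ens, 5, threshold = 1e-9)
  sel_e <- select_lowest_energy(ens, 5)
  expect_equal(ens_energies(sel_f), ens_energies(sel_e))
})

test_that("duplicate conformers keep only the lowest-energy copy", {
  xyz <- chain_coords(c(-180, -180, -180))
  ens <- conf_ensemble(chain_fix$mol, list(
    conformer(xyz, energy = 2), conformer(xyz, energy = 1),
    conformer(xyz, energy = 3)))
  sel <- select_energy_rmsd_filtered(ens, 3, threshold = 0.5)
  expect_equal(length(sel), 1L)
  expect_equal(sel$conformers[[1]]$energy, 1)
})

test_that("greedy filter equals the independent trace on random ensembles", {
  withr::with_seed(31, {
    for (trial in 1:40) {
      n <- sample(4:12, 1)
      ens <- make_ensemble(chain_fix, n, mixing_weight = 0.2,
                           noise_sigma = 0.4, seed = sample.int(1e6, 1))
      thr <- runif(1, 0.3, 2.5)
      max_n <- sample(1:n, 1)
      sel <- select_energy_rmsd_filtered(ens, max_n, thr)
      trace_idx <- greedy_trace(ens, max_n, thr)
      got <- vapply(sel$conformers, function(cf) cf$provenance$sample,
                    integer(1))
      expect_identical(got, vapply(ens$conformers[trace_idx],
                                   function(cf) cf$provenance$sample,
                                   integer(1)))
      # every selected pair exceeds the threshold
      if (length(sel) > 1) {
        for (i in 1:(length(sel) - 1)) for (j in (i + 1):length(sel)) {
          expect_gt(as.numeric(symmetry_rmsd(sel$conformers[[i]],
                                             sel$conformers[[j]],
                                             sel$molecule)), thr)
        }
      }
      # first selected conformer is the global energy minimum
      e <- ens_energies(ens)
      expect_equal(sel$conformers[[1]]$energy, min(e))
    }
  })
})

test_that("raising the threshold never increases the selected count", {
  ens <- make_ensemble(chain_fix, 40, mixing_weight = 0.1, noise_sigma = 0.3,
                       seed = 77)
  sizes <- vapply(c(0.5, 1.0, 1.5, 2.0), function(t)
    length(select_energy_rmsd_filtered(ens, 40, t)), integer(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("apply_policy dispatches and preserves provenance", {
  ens <- ens_with_energies(c(4, 1, 3, 2))
  p1 <- selection_policy("lowest_energy", 1)
  expect_equal(apply_policy(ens, p1)$conformers[[1]]$energy, 1)
  p2 <- selection_policy("energy_rmsd_filtered", 10, rmsd_threshold = 1000)
  expect_equal(length(apply_policy(ens, p2)), 1L)  # nothing else passes
  p3 <- selection_policy("unbiased", 2, seed = 5)
  s1 <- apply_policy(ens, p3); s2 <- apply_policy(ens, p3)
  expect_identical(ens_energies(s1), ens_energies(s2))
  expect_true(all(c("generator", "sample") %in%
                    names(s1$conformers[[1]]$provenance)))
})

test_that("selection output is always a subset without repeats", {
  withr::with_seed(41, {
    ens <- make_ensemble(chain_fix, 15, mixing_weight = 0.2, seed = 3)
    for (pol in list(selection_policy("unbiased", 6, seed = 2),
                     selection_policy("lowest_energy", 6),
                     selection_policy("energy_rmsd_filtered", 6,
                                      rmsd_threshold = 0.8))) {
      sel <- apply_policy(ens, pol)
      idx <- vapply(sel$conformers, function(cf) cf$provenance$sample,
                    integer(1))
      expect_lte(length(sel), 6L)
      expect_false(anyDuplicated(idx) > 0)
      expect_true(all(idx %in% 1:15))
    }
  })
})
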