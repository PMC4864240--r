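test_that("poseRMSD matches hand calculations and errors on mismatched atoms", {
  base <- baseGeometry(5)
  expect_identical(poseRMSD(base, base), 0)
  expect_equal(poseRMSD(base, translatedPose(base, 3, 0, 0)), 3)

  a <- matrix(c(0, 0, 0, 1, 0, 0), ncol = 3, byrow = TRUE)
  b <- matrix(c(0, 0, 0, 3, 0, 0), ncol = 3, byrow = TRUE)
  expect_equal(poseRMSD(a, b), sqrt(4 / 2))
  expect_equal(poseRMSD(a, b), poseRMSD(b, a))

  expect_error(poseRMSD(a, matrix(0, 3, 3)), "atom-count mismatch")
})

test_that("clusterPoses separates well-spaced groups and handles degenerate input", {
  base <- baseGeometry(6)
  set.seed(5)
  grpA <- lapply(1:5, function(i) base + matrix(rnorm(18, sd = 0.1), 6, 3))
  grpB <- lapply(1:4, function(i)
    translatedPose(base, 10, 0, 0) + matrix(rnorm(18, sd = 0.1), 6, 3))
  ens <- makeEnsemble(c(grpA, grpB))
  clusters <- clusterPoses(ens, rmsdCutoff = 2)
  expect_length(clusters, 2L)
  sizes <- sort(vapply(clusters, function(x) length(memberIndices(x)),
                       integer(1)))
  expect_identical(sizes, c(4L, 5L))
  # membership matches the construction
  mem <- lapply(clusters, memberIndices)
  expect_true(setequal(mem[[which.max(lengths(mem))]], 1:5))

  single <- makeEnsemble(list(base))
  expect_length(clusterPoses(single, 2), 1L)

  same <- makeEnsemble(rep(list(base), 7))
  cl <- clusterPoses(same, 2)
  expect_length(cl, 1L)
  expect_length(memberIndices(cl[[1L]]), 7L)
})

test_that("leader clustering satisfies the exhaustive pairwise-distance oracle", {
  set.seed(77)
  for (rep in 1:40) {
    n <- sample(2:12, 1)
    nAtoms <- sample(3:8, 1)
    # mixture of tight groups and scattered poses
    centers <- lapply(1:sample(1:3, 1), function(i)
      matrix(rnorm(nAtoms * 3, sd = 4), nAtoms, 3))
    poses <- lapply(seq_len(n), function(i) {
      ctr <- centers[[sample(length(centers), 1)]]
      ctr + matrix(rnorm(nAtoms * 3, sd = runif(1, 0.05, 2)), nAtoms, 3)
    })
    ens <- makeEnsemble(poses, energy = rnorm(n, -6))
    cutoff <- runif(1, 0.5, 5)
    clusters <- clusterPoses(ens, cutoff)
    D <- oracleRmsdMatrix(ens)

    # every pose assigned exactly once
    allMembers <- sort(unlist(lapply(clusters, memberIndices)))
    expect_identical(allMembers, seq_len(n))
    # members within cutoff of their representative
    for (cl in clusters)
      expect_true(all(D[cl@representativeIdx, memberIndices(cl)] <=
                        cutoff + 1e-12))
    # representatives pairwise separated by more than the cutoff
    reps <- vapply(clusters, function(cl) cl@representativeIdx, integer(1))
    if (length(reps) > 1L) {
      sub <- D[reps, reps, drop = FALSE]
      expect_true(all(sub[upper.tri(sub)] > cutoff))
    }
  }
})

test_that("selectRepresentative maximises model coverage with stated tie-breaks", {
  base <- baseGeometry(4)
  mkCluster <- function(models, energies, offset) {
    n <- length(models)
    poses <- lapply(seq_len(n), function(i)
      translatedPose(base, offset, 0, 0) + matrix(rnorm(12, sd = 0.05), 4, 3))
    ens <- makeEnsemble(poses, energy = energies, modelId = models,
                        nModels = 10)
    clusterPoses(ens, 2)[[1L]]
  }
  set.seed(3)
  c5 <- mkCluster(1:5, rep(-5, 5), 0)
  c3 <- mkCluster(1:3, rep(-7, 3), 20)
  c2 <- mkCluster(1:2, rep(-8, 2), 40)
  expect_identical(selectRepresentative(list(c3, c2, c5)), c5)

  # tie on coverage: lower mean energy wins
  cA <- mkCluster(1:4, rep(-6.1, 4), 0)
  cB <- mkCluster(1:4, rep(-5.0, 4), 20)
  expect_identical(selectRepresentative(list(cB, cA)), cA)

  # permutation invariance
  perms <- list(list(c5, c3, c2), list(c2, c5, c3), list(c3, c2, c5))
  picks <- lapply(perms, selectRepresentative)
  expect_identical(picks[[1L]], picks[[2L]])
  expect_identical(picks[[2L]], picks[[3L]])

  expect_error(selectRepresentative(list()), "no clusters")
})

test_that("aggregateEnergy averages the best pose per represented model", {
  base <- baseGeometry(4)
  set.seed(9)
  mk <- function(models, energies) {
    poses <- lapply(seq_along(models), function(i)
      base + matrix(rnorm(12, sd = 0.05), 4, 3))
    ens <- makeEnsemble(poses, energy = energies, modelId = models,
                        poseIndex = seq_along(models), nModels = 10)
    clusterPoses(ens, 2)[[1L]]
  }
  one <- aggregateEnergy(mk(1L, -6))
  expect_equal(one$meanEnergy, -6)
  expect_equal(one$sdEnergy, 0)

  three <- aggregateEnergy(mk(1:3, c(-6, -7, -8)))
  expect_equal(three$meanEnergy, -7)
  expect_equal(three$sdEnergy, 1)

  # two poses from the SAME model: only the better one counts
  dup <- aggregateEnergy(mk(c(2L, 2L), c(-6.2, -5.0)))
  expect_equal(dup$meanEnergy, -6.2)
  expect_equal(dup$sdEnergy, 0)
})

test_that("kdFromEnergy implements Kd = exp(dG/RT) and round-trips exactly", {
  RT <- 1.9872e-3 * 300
  expect_equal(kdFromEnergy(0), 1)
  expect_equal(kdFromEnergy(RT), exp(1))
  expect_equal(kdFromEnergy(-6.8635) * 1e6, 10.0, tolerance = 1e-3)
  # strictly increasing in dG
  expect_true(all(diff(kdFromEnergy(seq(-10, 0, by = 0.5))) > 0))

  set.seed(31)
  for (kd in 10^runif(25, -9, -2)) {
    back <- kdFromEnergy(energyFromKd(kd))
    expect_lt(abs(back - kd) / kd, 1e-12)
  }
  expect_error(kdFromEnergy(-5, temperature = 0), "positive")
})

test_that("occupancyWeightedKd applies the free/bound weight with the free=0 convention", {
  even <- occupancyWeightedKd(10, 50, 50)
  expect_equal(even$weightedKd, 10)
  expect_false(even$degenerate)

  skewed <- occupancyWeightedKd(10, 80, 20)
  expect_equal(skewed$weightedKd, 2.5)

  allBound <- occupancyWeightedKd(10, 100, 0)
  expect_equal(allBound$weightedKd, 10)
  expect_true(allBound$degenerate)

  expect_error(occupancyWeightedKd(10, 0, 100), "bound")

  # monotone non-increasing in bound at fixed kd and total models
  w <- vapply(1:100, function(b)
    occupancyWeightedKd(10, b, 100 - b)$weightedKd, numeric(1))
  expect_true(all(diff(w[1:99]) <= 0))
})

test_that("consensusPipeline composes the stages on a planted ensemble", {
  pe <- simulatePoseEnsemble(nModels = 100, occupancy = 0.6,
                             energyMean = -6.8635, energySd = 0,
                             maxJitter = 0, seed = 17)
  res <- consensusPipeline(pe)
  expect_equal(res@bound, 60L)
  expect_equal(res@free, 40L)
  expect_equal(res@meanEnergy, -6.8635)
  expect_equal(res@sdEnergy, 0)
  expect_equal(res@kdMicromolar, 10.0, tolerance = 1e-3)
  expect_equal(res@weightedKd, res@kdMicromolar * 40 / 60)
  expect_false(res@degenerate)

  # single model, single pose: degenerate weighting
  one <- makeEnsemble(list(baseGeometry(4)), energy = -6, nModels = 1)
  r1 <- consensusPipeline(one)
  expect_equal(r1@bound, 1L)
  expect_equal(r1@free, 0L)
  expect_true(r1@degenerate)
  expect_equal(r1@weightedKd, r1@kdMicromolar)
})

test_that("the consensus pipeline is invariant to pose order and model relabeling", {
  pe <- simulatePoseEnsemble(nModels = 30, occupancy = 0.6, seed = 23)
  res <- consensusPipeline(pe)

  reorder <- function(ens, perm) {
    PoseEnsemble(ens@proteinId, ens@ligandId, ens@nModels,
                 ens@modelId[perm], ens@poseIndex[perm], ens@energy[perm],
                 ens@coords[, , perm, drop = FALSE])
  }
  set.seed(1)
  perm <- sample(nPoses(pe))
  resPerm <- consensusPipeline(reorder(pe, perm))
  for (sl in c("meanEnergy", "sdEnergy", "kd", "bound", "free",
               "weightedKd", "degenerate"))
    expect_identical(slot(resPerm, sl), slot(res, sl))
  expect_identical(sort(resPerm@clusterSizes), sort(res@clusterSizes))

  # bijective relabeling of model ids preserves all counts
  relabel <- sample(nModels(pe))
  pe2 <- PoseEnsemble(pe@proteinId, pe@ligandId, pe@nModels,
                      relabel[pe@modelId], pe@poseIndex, pe@energy, pe@coords)
  res2 <- consensusPipeline(pe2)
  for (sl in c("meanEnergy", "sdEnergy", "kd", "bound", "free", "weightedKd"))
    expect_identical(slot(res2, sl), slot(res, sl))
})

test_that("counting population by poses is available as a switch", {
  base <- baseGeometry(4)
  set.seed(2)
  # 3 poses all from model 1 at site A; 2 poses from models 2 and 3 at site B
  siteA <- lapply(1:3, function(i) base + matrix(rnorm(12, sd = 0.05), 4, 3))
  siteB <- lapply(1:2, function(i)
    translatedPose(base, 15, 0, 0) + matrix(rnorm(12, sd = 0.05), 4, 3))
  ens <- makeEnsemble(c(siteA, siteB), energy = c(-8, -7.9, -7.8, -6, -5.9),
                      modelId = c(1L, 1L, 1L, 2L, 3L),
                      poseIndex = c(1L, 2L, 3L, 1L, 1L), nModels = 3)
  clusters <- clusterPoses(ens, 2)
  byModels <- selectRepresentative(clusters, countBy = "models")
  byPoses <- selectRepresentative(clusters, countBy = "poses")
  expect_identical(modelsRepresented(byModels), 2L)  # site B covers 2 models
  expect_identical(length(memberIndices(byPoses)), 3L)  # site A has 3 poses
})
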