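#' @include AllClasses.R
NULL

## A fresh allele: a sparse attraction/repulsion profile over odorants,
## with 1..maxLigands ligands, each +1 or -1 with equal probability.
.newAllele <- function(nOdorants, maxLigands, forcedAR = NULL) {
  if (!is.null(forcedAR)) return(as.integer(forcedAR))
  ar <- integer(nOdorants)
  nLig <- sample.int(maxLigands, 1L)
  lig <- sample.int(nOdorants, min(nLig, nOdorants))
  ar[lig] <- sample(c(-1L, 1L), length(lig), replace = TRUE)
  ar
}

## Animal-level response to each odorant: per gene the sign of the two
## alleles' responses (heterozygous conflicts cancel), summed over genes.
.animalResponse <- function(genotype, poolAR) {
  g1 <- poolAR[genotype[1L, ], , drop = FALSE]
  g2 <- poolAR[genotype[2L, ], , drop = FALSE]
  colSums(sign(g1 + g2))
}

#' Initialize an odorant-driven simulation world
#'
#' Default configuration follows the simulated study design: a 200 x 200
#' grid with 50 odorant point sources placed uniformly at random, 40
#' founder animals packed in a central block, 100 diploid receptor genes
#' per animal with 1-14 ligands per allele (attraction or repulsion with
#' equal probability), 30\% mating probability for adjacent opposite-sex
#' pairs with at least 5 empty neighbouring cells, and a 5\% per-allele
#' mutation rate.
#'
#' The world's mutable state (positions, genotypes, allele pool,
#' occupancy) lives in an environment slot, so \code{\link{worldStep}}
#' updates it by reference; keep separate \code{initWorld} results for
#' independent replicates.
#'
#' @param gridDim length-2 grid dimensions.
#' @param nOdorants number of odorant sources.
#' @param nFounders number of founder animals.
#' @param nGenes receptor genes per animal (diploid).
#' @param maxLigands maximal ligands per allele.
#' @param fractionOdorDriven probability a move follows the
#'   attraction/repulsion vector rather than being random.
#' @param mateProb mating probability per eligible pair per step.
#' @param mutationRate per-inherited-allele random replacement rate.
#' @param minEmptyForMating empty 8-neighbour cells required around a
#'   parent.
#' @param seed RNG seed.
#' @param odorantPositions optional matrix of source coordinates
#'   (overrides random placement).
#' @param founderPositions optional matrix of founder coordinates.
#' @param forcedAR optional length-nOdorants response profile given to
#'   every founder allele (for constructed scenarios).
#' @return an \linkS4class{OdorWorld}.
#' @export
initWorld <- function(gridDim = c(200L, 200L), nOdorants = 50L,
                      nFounders = 40L, nGenes = 100L, maxLigands = 14L,
                      fractionOdorDriven = 0.5, mateProb = 0.3,
                      mutationRate = 0.05, minEmptyForMating = 5L,
                      seed = 1L, odorantPositions = NULL,
                      founderPositions = NULL, forcedAR = NULL) {
  set.seed(seed)
  gridDim <- as.integer(gridDim)
  if (is.null(odorantPositions)) {
    odorantPositions <- cbind(sample.int(gridDim[1], nOdorants,
                                         replace = TRUE),
                              sample.int(gridDim[2], nOdorants,
                                         replace = TRUE))
  } else {
    odorantPositions <- matrix(as.integer(odorantPositions), ncol = 2L)
    nOdorants <- nrow(odorantPositions)
  }
  if (is.null(founderPositions)) {
    # founders fill a centred square block, row-major
    side <- ceiling(sqrt(nFounders))
    if (side > min(gridDim)) stop("grid too small for founders")
    x0 <- (gridDim[1] - side) %/% 2L
    y0 <- (gridDim[2] - side) %/% 2L
    all <- expand.grid(x = x0 + seq_len(side), y = y0 + seq_len(side))
    founderPositions <- as.matrix(all[seq_len(nFounders), ])
  } else {
    founderPositions <- matrix(as.integer(founderPositions), ncol = 2L)
    nFounders <- nrow(founderPositions)
  }
  e <- new.env(parent = emptyenv())
  e$n <- nFounders
  e$x <- as.integer(founderPositions[, 1])
  e$y <- as.integer(founderPositions[, 2])
  e$sex <- sample(c("F", "M"), nFounders, replace = TRUE)
  poolN <- 2L * nGenes * nFounders
  pool <- matrix(0L, poolN, nOdorants)
  for (i in seq_len(poolN))
    pool[i, ] <- .newAllele(nOdorants, maxLigands, forcedAR)
  genotypes <- vector("list", nFounders)
  responses <- matrix(0, nFounders, nOdorants)
  for (a in seq_len(nFounders)) {
    ids <- (a - 1L) * 2L * nGenes + seq_len(2L * nGenes)
    g <- matrix(ids, nrow = 2L)
    genotypes[[a]] <- g
    responses[a, ] <- .animalResponse(g, pool)
  }
  e$poolN <- poolN
  e$poolAR <- pool
  e$genotypes <- genotypes
  e$responses <- responses
  occ <- matrix(0L, gridDim[1], gridDim[2])
  occ[cbind(e$x, e$y)] <- seq_len(nFounders)
  e$occupancy <- occ
  e$step <- 0L
  e$births <- list()
  methods::new("OdorWorld",
    gridDim = gridDim, odorants = odorantPositions,
    params = list(nGenes = as.integer(nGenes),
                  maxLigands = as.integer(maxLigands),
                  fractionOdorDriven = fractionOdorDriven,
                  mateProb = mateProb, mutationRate = mutationRate,
                  minEmptyForMating = as.integer(minEmptyForMating),
                  env = e),
    step = 0L)
}

.worldEnv <- function(w) w@params$env

#' Current animal table of a world
#'
#' @param w an \linkS4class{OdorWorld}.
#' @return data.frame: id, x, y, sex.
#' @rdname accessors
#' @export
worldAnimals <- function(w) {
  e <- .worldEnv(w)
  idx <- seq_len(e$n)
  data.frame(id = idx, x = e$x[idx], y = e$y[idx], sex = e$sex[idx],
             stringsAsFactors = FALSE)
}

#' Birth records of a world
#'
#' @param w an \linkS4class{OdorWorld}.
#' @return data.frame: child, mother, father, step (animal indices).
#' @export
birthRecords <- function(w) {
  e <- .worldEnv(w)
  if (!length(e$births))
    return(data.frame(child = integer(), mother = integer(),
                      father = integer(), step = integer()))
  m <- do.call(rbind, e$births)
  data.frame(child = m[, 1], mother = m[, 2], father = m[, 3],
             step = m[, 4])
}

#' Genotype of one animal
#'
#' @param w an \linkS4class{OdorWorld}.
#' @param animal animal index.
#' @return 2 x nGenes integer matrix of allele ids.
#' @export
worldGenotype <- function(w, animal) .worldEnv(w)$genotypes[[animal]]

#' Net attraction/repulsion vector of an animal
#'
#' Sums, over odorant sources, the animal's net response to the odorant
#' divided by the distance, times the unit vector toward the source:
#' m_a = sum_i (AR_i / d_ia) (o_i - p_a) / ||o_i - p_a||. Sources the
#' animal sits on exactly are skipped. A zero vector means the animal
#' moves randomly.
#'
#' @param w an \linkS4class{OdorWorld}.
#' @param animal animal index.
#' @return numeric length-2 vector.
#' @export
attractionVector <- function(w, animal) {
  e <- .worldEnv(w)
  dx <- w@odorants[, 1] - e$x[animal]
  dy <- w@odorants[, 2] - e$y[animal]
  ar <- e$responses[animal, ]
  d2 <- dx * dx + dy * dy
  sel <- ar != 0 & d2 > 0
  if (!any(sel)) return(c(0, 0))
  # AR/d * unit(o - p) = AR * (o - p) / d^2
  coef <- ar[sel] / d2[sel]
  c(sum(coef * dx[sel]), sum(coef * dy[sel]))
}

.neighbours8 <- matrix(c(-1L, -1L, -1L, 0L, -1L, 1L, 0L, -1L, 0L, 1L,
                         1L, -1L, 1L, 0L, 1L, 1L), ncol = 2L, byrow = TRUE)

## Movement phase. State vectors are moved out of the environment into
## locals for the duration of the phase (complex assignment on an
## environment binding copies the whole object every write; on a local
## with reference count 1 it is in place), then written back once.
.movePhase <- function(w, e) {
  n <- e$n
  occ <- e$occupancy; e$occupancy <- NULL
  x <- e$x; e$x <- NULL
  y <- e$y; e$y <- NULL
  ox <- w@odorants[, 1]; oy <- w@odorants[, 2]
  gx <- w@gridDim[1]; gy <- w@gridDim[2]
  frac <- w@params$fractionOdorDriven
  for (a in sample.int(n)) {
    delta <- NULL
    if (stats::runif(1) < frac) {
      ar <- e$responses[a, ]
      dx <- ox - x[a]; dy <- oy - y[a]
      d2 <- dx * dx + dy * dy
      sel <- ar != 0 & d2 > 0
      if (any(sel)) {
        coef <- ar[sel] / d2[sel]
        mx <- sum(coef * dx[sel]); my <- sum(coef * dy[sel])
        nrm <- sqrt(mx * mx + my * my)
        if (nrm > 0)
          delta <- pmax(-1L, pmin(1L, as.integer(round(c(mx, my) / nrm))))
      }
    }
    if (is.null(delta))
      delta <- .neighbours8[sample.int(8L, 1L), ]
    tx <- x[a] + delta[1]; ty <- y[a] + delta[2]
    if (tx < 1L || tx > gx || ty < 1L || ty > gy) next
    if (occ[tx, ty] != 0L) next
    occ[x[a], y[a]] <- 0L
    occ[tx, ty] <- a
    x[a] <- tx; y[a] <- ty
  }
  e$occupancy <- occ; e$x <- x; e$y <- y
  invisible(NULL)
}

.emptyCells <- function(occ, gx, gy, px, py) {
  cells <- cbind(px + .neighbours8[, 1], py + .neighbours8[, 2])
  ok <- cells[, 1] >= 1L & cells[, 1] <= gx &
        cells[, 2] >= 1L & cells[, 2] <= gy
  cells <- cells[ok, , drop = FALSE]
  cells[occ[cells] == 0L, , drop = FALSE]
}

#' Cross two parental genotypes into an offspring genotype
#'
#' Per gene, one allele is drawn uniformly from each parent's pair; each
#' inherited allele is then independently replaced by a brand-new random
#' allele with the mutation probability. New alleles get fresh ids, so a
#' mutated allele id never occurs in either parent.
#'
#' @param motherG,fatherG 2 x nGenes allele-id matrices.
#' @param poolAR current allele pool (alleles x odorants).
#' @param mutationRate per-allele replacement probability.
#' @param maxLigands ligands per new allele (1..maxLigands).
#' @return list: \code{genotype} (2 x nGenes), \code{poolAR} (possibly
#'   grown), \code{nAlleles} (alleles now in use).
#' @export
crossGenotypes <- function(motherG, fatherG, poolAR, mutationRate,
                           maxLigands = 14L) {
  G <- ncol(motherG)
  child <- rbind(motherG[cbind(sample(2L, G, replace = TRUE), seq_len(G))],
                 fatherG[cbind(sample(2L, G, replace = TRUE), seq_len(G))])
  mut <- matrix(stats::runif(2L * G) < mutationRate, nrow = 2L)
  nMut <- sum(mut)
  nAlleles <- nrow(poolAR)
  if (nMut > 0L) {
    newRows <- matrix(0L, nMut, ncol(poolAR))
    for (i in seq_len(nMut))
      newRows[i, ] <- .newAllele(ncol(poolAR), maxLigands)
    child[mut] <- nAlleles + seq_len(nMut)
    poolAR <- rbind(poolAR, newRows)
    nAlleles <- nAlleles + nMut
  }
  list(genotype = child, poolAR = poolAR, nAlleles = nAlleles)
}

## Mating phase: each female may mate once per step with a random
## adjacent male, with probability mateProb, provided one of the parents
## has >= minEmptyForMating empty neighbouring cells; the offspring is
## placed on a random empty cell adjacent to that parent. Uses the same
## local-state pattern as .movePhase to keep writes in place.
.matePhase <- function(w, e) {
  n <- e$n
  females <- which(e$sex[seq_len(n)] == "F")
  if (!length(females)) return(invisible(NULL))
  if (length(females) > 1L) females <- sample(females)
  minEmpty <- w@params$minEmptyForMating
  mutationRate <- w@params$mutationRate
  maxLigands <- w@params$maxLigands
  gx <- w@gridDim[1]; gy <- w@gridDim[2]
  occ <- e$occupancy; e$occupancy <- NULL
  x <- e$x; e$x <- NULL
  y <- e$y; e$y <- NULL
  sex <- e$sex; e$sex <- NULL
  resp <- e$responses; e$responses <- NULL
  pool <- e$poolAR; e$poolAR <- NULL
  poolN <- e$poolN
  genotypes <- e$genotypes; e$genotypes <- NULL
  births <- e$births; e$births <- NULL
  nOdor <- ncol(pool)
  for (f in females) {
    cells <- cbind(x[f] + .neighbours8[, 1], y[f] + .neighbours8[, 2])
    ok <- cells[, 1] >= 1L & cells[, 1] <= gx &
          cells[, 2] >= 1L & cells[, 2] <= gy
    neigh <- occ[cells[ok, , drop = FALSE]]
    males <- neigh[neigh != 0L]
    males <- males[sex[males] == "M"]
    if (!length(males)) next
    m <- if (length(males) == 1L) males else sample(males, 1L)
    if (stats::runif(1) >= w@params$mateProb) next
    emptyF <- .emptyCells(occ, gx, gy, x[f], y[f])
    parent <- if (nrow(emptyF) >= minEmpty) f else {
      emptyM <- .emptyCells(occ, gx, gy, x[m], y[m])
      if (nrow(emptyM) >= minEmpty) m else next
    }
    empty <- if (parent == f) emptyF else
      .emptyCells(occ, gx, gy, x[parent], y[parent])
    cell <- empty[sample.int(nrow(empty), 1L), ]
    # offspring genotype: one allele per gene from each parent, then
    # per-allele mutation to a brand-new allele
    G <- w@params$nGenes
    mg <- genotypes[[f]]; fg <- genotypes[[m]]
    child <- rbind(mg[cbind(sample(2L, G, replace = TRUE), seq_len(G))],
                   fg[cbind(sample(2L, G, replace = TRUE), seq_len(G))])
    mut <- matrix(stats::runif(2L * G) < mutationRate, nrow = 2L)
    nMut <- sum(mut)
    if (nMut > 0L) {
      if (poolN + nMut > nrow(pool))
        pool <- rbind(pool, matrix(0L, max(poolN + nMut, nrow(pool)),
                                   nOdor))
      for (i in seq_len(nMut))
        pool[poolN + i, ] <- .newAllele(nOdor, maxLigands)
      child[mut] <- poolN + seq_len(nMut)
      poolN <- poolN + nMut
    }
    n <- n + 1L
    if (n > length(x)) {
      pad <- length(x)
      x <- c(x, integer(pad)); y <- c(y, integer(pad))
      sex <- c(sex, character(pad))
      resp <- rbind(resp, matrix(0, pad, nOdor))
    }
    x[n] <- cell[1]; y[n] <- cell[2]
    sex[n] <- sample(c("F", "M"), 1L)
    genotypes[[n]] <- child
    resp[n, ] <- .animalResponse(child, pool)
    occ[cell[1], cell[2]] <- n
    births[[length(births) + 1L]] <- c(n, f, m, e$step)
  }
  e$n <- n
  e$occupancy <- occ; e$x <- x; e$y <- y; e$sex <- sex
  e$responses <- resp; e$poolAR <- pool; e$poolN <- poolN
  e$genotypes <- genotypes; e$births <- births
  invisible(NULL)
}

#' Advance the world by one step
#'
#' Movement phase (animals updated in a fresh random permutation; moves
#' onto occupied or out-of-bounds cells are cancelled) followed by the
#' mating phase. The world state is updated in place and the world
#' returned.
#'
#' @param w an \linkS4class{OdorWorld}.
#' @return \code{w}, with its state advanced one step.
#' @export
worldStep <- function(w) {
  e <- .worldEnv(w)
  e$step <- e$step + 1L
  .movePhase(w, e)
  .matePhase(w, e)
  w@step <- e$step
  w
}

#' Mean pairwise genotype mismatch (genetic diversity)
#'
#' For each pair of animals and each gene, the mismatch is 1 minus half
#' the multiset intersection of the two allele pairs; diversity is the
#' mean over genes and pairs. A clonal population scores 0, two animals
#' sharing no allele score 1. Beyond \code{maxPairs} pairs a uniform
#' random sample of pairs is used.
#'
#' @param w an \linkS4class{OdorWorld} with >= 2 animals.
#' @param maxPairs cap on the number of pairs evaluated.
#' @return diversity in [0, 1].
#' @export
diversityMetric <- function(w, maxPairs = 2000L) {
  e <- .worldEnv(w)
  n <- e$n
  stopifnot(n >= 2L)
  if (choose(n, 2L) <= maxPairs) {
    pairs <- utils::combn(n, 2L)
  } else {
    i <- sample.int(n, maxPairs, replace = TRUE)
    j <- sample.int(n - 1L, maxPairs, replace = TRUE)
    j <- ifelse(j >= i, j + 1L, j)
    pairs <- rbind(pmin(i, j), pmax(i, j))
  }
  mism <- apply(pairs, 2L, function(pr) {
    A <- e$genotypes[[pr[1]]]; B <- e$genotypes[[pr[2]]]
    m11 <- A[1, ] == B[1, ]; m12 <- A[1, ] == B[2, ]
    m21 <- A[2, ] == B[1, ]; m22 <- A[2, ] == B[2, ]
    shared <- ifelse((m11 & m22) | (m12 & m21), 2L,
                     (m11 | m12 | m21 | m22) * 1L)
    mean(1 - shared / 2)
  })
  mean(mism)
}

#' Number of spatial communities
#'
#' Connected components of animals linked when within Chebyshev distance
#' \code{radius} of each other (read off the occupancy grid).
#'
#' @param w an \linkS4class{OdorWorld}.
#' @param radius linking distance (grid units).
#' @return the component count.
#' @export
communityCount <- function(w, radius = 2L) {
  e <- .worldEnv(w)
  n <- e$n
  if (n == 0L) return(0L)
  offs <- expand.grid(dx = -radius:radius, dy = -radius:radius)
  offs <- offs[!(offs$dx == 0L & offs$dy == 0L), ]
  comp <- integer(n)
  nComp <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    nComp <- nComp + 1L
    queue <- s
    comp[s] <- nComp
    while (length(queue)) {
      i <- queue[[1L]]; queue <- queue[-1L]
      cx <- e$x[i] + offs$dx; cy <- e$y[i] + offs$dy
      ok <- cx >= 1L & cx <= w@gridDim[1] & cy >= 1L & cy <= w@gridDim[2]
      nb <- e$occupancy[cbind(cx[ok], cy[ok])]
      nb <- nb[nb != 0L]
      new <- nb[comp[nb] == 0L]
      comp[new] <- nComp
      queue <- c(queue, new)
    }
  }
  nComp
}

#' Run a simulation and record metrics
#'
#' Applies \code{\link{worldStep}} repeatedly, recording population size,
#' community count and genetic diversity every \code{recordEvery} steps
#' (and at steps 0 and nSteps). Optionally keeps per-step position
#' snapshots.
#'
#' @param w an initialized \linkS4class{OdorWorld}.
#' @param nSteps number of steps.
#' @param recordEvery metric recording interval.
#' @param snapshots record per-step animal positions (id, x, y)?
#' @return list: \code{world} (final state), \code{metrics} (data.frame:
#'   step, population, communities, diversity), \code{snapshots} (list of
#'   data.frames, or NULL).
#' @export
runWorld <- function(w, nSteps, recordEvery = 10L, snapshots = FALSE) {
  e <- .worldEnv(w)
  record <- function() data.frame(
    step = e$step, population = e$n,
    communities = communityCount(w),
    diversity = if (e$n >= 2L) diversityMetric(w) else NA_real_)
  metrics <- list(record())
  snaps <- if (snapshots) list(worldAnimals(w)[c("id", "x", "y")]) else NULL
  for (s in seq_len(nSteps)) {
    w <- worldStep(w)
    if (s %% recordEvery == 0L || s == nSteps)
      metrics[[length(metrics) + 1L]] <- record()
    if (snapshots)
      snaps[[length(snaps) + 1L]] <- worldAnimals(w)[c("id", "x", "y")]
  }
  list(world = w, metrics = unique(do.call(rbind, metrics)),
       snapshots = snaps)
}
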