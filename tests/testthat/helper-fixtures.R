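# Shared fixtures, all built in code.

# Small generator config for fast end-to-end runs.
smallConfig <- function(seed = 1L, ...) {
  syntheticConfig(nIndividuals = 50L, nFamilies = 2L,
                  membersPerFamily = c(4L, 5L), modelLength = c(20L, 30L),
                  seed = seed, ...)
}

# Hand-built family: 3 members, model length 6.
#  P1: identity map, domain at 3..8 of a 10-residue protein.
#  P2: gap at column 4 (5 domain residues), insertion of 1 residue after
#      column 2.
#  P3: identity map starting at residue 1.
toyAlignment <- function() {
  members <- data.frame(protein = c("P1", "P2", "P3"),
                        start = c(3L, 2L, 1L), end = c(8L, 7L, 6L),
                        stringsAsFactors = FALSE)
  columnMaps <- list(P1 = 1:6,
                     P2 = c(1L, 2L, NA, 3L, 5L, 6L),
                     P3 = 1:6)
  residueMatrix <- rbind(
    P1 = c("D", "R", "Y", "A", "K", "L"),
    P2 = c("D", "R", "Y", NA, "K", "L"),
    P3 = c("D", "R", "F", "A", "K", "V"))
  colnames(residueMatrix) <- NULL
  computeConsensus(new("FamilyAlignment", family = "TOY",
                       modelLength = 6L, members = members,
                       columnMaps = columnMaps,
                       residueMatrix = residueMatrix,
                       consensus = data.frame()))
}

# Protein sequences consistent with toyAlignment (flanks are arbitrary).
toyProteins <- function() {
  Biostrings::AAStringSet(c(
    P1 = "GGDRYAKLGG",        # domain at 3..8
    P2 = "GDRWYKLGGG",        # W inserted after column 2, gap at column 4
    P3 = "DRFAKVGGGG"))       # domain at 1..6
}

# Tiny variant set over the toy proteins: 3 individuals.
toyVariantSet <- function() {
  variants <- data.frame(
    protein = c("P1", "P1", "P2", "P3"),
    position = c(4L, 9L, 3L, 2L),
    ref = c("R", "G", "R", "R"),
    alt = c("H", "D", "C", "Q"),
    consequence = c("missense", "missense", "missense", "missense"),
    stringsAsFactors = FALSE)
  geno <- matrix(c(1L, 0L, 0L,
                   0L, 0L, 2L,
                   1L, 1L, 0L,
                   0L, 2L, 1L), nrow = 4L, byrow = TRUE,
                 dimnames = list(NULL, c("I1", "I2", "I3")))
  cohortDf <- data.frame(id = c("I1", "I2", "I3"),
                         subpop = c("A", "A", "B"),
                         sex = c("F", "M", "F"), stringsAsFactors = FALSE)
  new("VariantSet", variants = variants, geno = geno, cohort = cohortDf)
}

# Brute-force placement oracle for per-column observed/expected counts:
# every allele is placed explicitly and every instance scanned one by one.
bruteForceColumnCounts <- function(vs, proteome) {
  idx <- domainIndex(proteome)
  inst <- idx$instances
  v <- variantInfo(vs)
  pooled <- alleleCounts(vs)
  mis <- v$consequence == "missense"
  totalAlleles <- sum(pooled[mis])
  proteomeLength <- sum(Biostrings::width(proteome@proteins))
  out <- list()
  for (fa in proteome@alignments) {
    obs <- numeric(fa@modelLength)
    for (r in which(mis)) {
      for (k in seq_len(pooled[r])) {        # one allele at a time
        for (i in seq_len(nrow(inst))) {
          if (inst$protein[i] != v$protein[r]) next
          if (inst$family[i] != fa@family) next
          if (v$position[r] < inst$start[i] ||
              v$position[r] > inst$end[i]) next
          col <- idx$maps[[i]][v$position[r] - inst$start[i] + 1L]
          if (!is.na(col)) obs[col] <- obs[col] + 1
        }
      }
    }
    # expectation accumulated instance by instance
    expc <- numeric(fa@modelLength)
    for (i in seq_len(nrow(inst))) {
      if (inst$family[i] != fa@family) next
      expc <- expc + totalAlleles / proteomeLength
    }
    out[[fa@family]] <- data.frame(column = seq_len(fa@modelLength),
                                   observed = obs, expected = expc)
  }
  out
}

# Rand index between two partitions (oracle implemented directly).
randIndex <- function(a, b) {
  n <- length(a)
  agree <- 0
  for (i in seq_len(n - 1L)) {
    sameA <- a[(i + 1L):n] == a[i]
    sameB <- b[(i + 1L):n] == b[i]
    agree <- agree + sum(sameA == sameB)
  }
  agree / choose(n, 2)
}
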