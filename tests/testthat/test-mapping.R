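test_that("variants map onto columns through the instance maps", {
  fa <- toyAlignment()
  idx <- domainIndex(list(fa))
  # identity mapping: P3 starts at 1, residue 5 -> column 5
  expect_equal(mapVariantToColumn("P3", 5L, idx),
               data.frame(family = "TOY", column = 5L,
                          stringsAsFactors = FALSE))
  # P1 domain starts at residue 3: residue 3 -> column 1
  expect_equal(mapVariantToColumn("P1", 3L, idx)$column, 1L)
  # insertion residue in P2 (position 4 = inserted W) maps nowhere
  expect_equal(nrow(mapVariantToColumn("P2", 4L, idx)), 0L)
  # outside every domain
  expect_equal(nrow(mapVariantToColumn("P1", 10L, idx)), 0L)
  expect_equal(nrow(mapVariantToColumn("UNKNOWN", 1L, idx)), 0L)
})

test_that("a protein with two instances of one family yields two hits", {
  members <- data.frame(protein = c("PX", "PX"), start = c(1L, 11L),
                        end = c(4L, 14L), stringsAsFactors = FALSE)
  maps <- list(PX = 1:4, PX = 1:4)
  rm2 <- matrix("A", 2, 4)
  fa <- new("FamilyAlignment", family = "DUP", modelLength = 4L,
            members = members, columnMaps = maps, residueMatrix = rm2,
            consensus = data.frame())
  hits <- mapVariantToColumn("PX", 2L, domainIndex(list(fa)))
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$column, 2L)
  hits2 <- mapVariantToColumn("PX", 12L, domainIndex(list(fa)))
  expect_equal(hits2$column, 2L)
})

test_that("consensus takes the modal residue with alphabetical ties", {
  rm10 <- matrix(rep("R", 10), ncol = 1)
  fa <- new("FamilyAlignment", family = "F", modelLength = 1L,
            members = data.frame(protein = sprintf("p%d", 1:10),
                                 start = 1L, end = 1L),
            columnMaps = rep(list(1L), 10), residueMatrix = rm10,
            consensus = data.frame())
  cons <- consensus(computeConsensus(fa, 0.5))
  expect_equal(cons$residue, "R")
  expect_true(cons$conserved)

  rmTie <- matrix(c(rep("R", 5), rep("K", 5)), ncol = 1)
  fa@residueMatrix <- rmTie
  consTie <- consensus(computeConsensus(fa, 0.5))
  expect_equal(consTie$residue, "K")        # alphabetical tie-break
  expect_true(consTie$conserved)            # 0.5 >= 0.5, inclusive
  expect_false(consensus(computeConsensus(fa, 0.6))$conserved)
})

test_that("dRy-style casing: conserved flags follow the threshold", {
  # column 1: D in 7/10; column 2: R in 10/10; column 3: Y in 4/10
  rm3 <- cbind(c(rep("D", 7), "E", "E", "N"),
               rep("R", 10),
               c(rep("Y", 4), "F", "F", "H", "H", "W", "L"))
  fa <- new("FamilyAlignment", family = "GPCR", modelLength = 3L,
            members = data.frame(protein = sprintf("p%d", 1:10),
                                 start = 1L, end = 3L),
            columnMaps = rep(list(1:3), 10), residueMatrix = rm3,
            consensus = data.frame())
  cons <- consensus(computeConsensus(fa, 0.5))
  expect_equal(cons$residue, c("D", "R", "Y"))
  expect_equal(cons$conserved, c(TRUE, TRUE, FALSE))   # "dRy" -> D, R only
})

test_that("consensus is invariant to member order", {
  fa <- toyAlignment()
  perm <- c(3L, 1L, 2L)
  fa2 <- new("FamilyAlignment", family = fa@family,
             modelLength = fa@modelLength,
             members = fa@members[perm, ],
             columnMaps = fa@columnMaps[perm],
             residueMatrix = fa@residueMatrix[perm, ],
             consensus = data.frame())
  expect_equal(consensus(computeConsensus(fa2)), consensus(fa))
})

test_that("canonicalCheck flags receptors by consensus residue", {
  fa <- toyAlignment()
  prots <- toyProteins()
  # P1 has R at column 2 (consensus R) and Y at column 3 (consensus Y)
  res <- canonicalCheck(prots["P1"], fa, c(2L, 3L), receptor = "P1")
  expect_equal(res$status, c("canonical", "canonical"))
  # P3 has F at column 3 where the consensus is Y
  res3 <- canonicalCheck(prots["P3"], fa, 3L, receptor = "P3")
  expect_equal(res3$status, "non_canonical")
  # P2 has a gap at column 4
  res2 <- canonicalCheck(prots["P2"], fa, 4L, receptor = "P2")
  expect_equal(res2$status, "unknown")
  expect_error(canonicalCheck(prots["P1"], fa, 1L, receptor = "NOPE"),
               "not a member")
})

test_that("a planted set of non-canonical receptors is recovered exactly", {
  # 100 family members, 24 built without the conserved arginine at one
  # column (the consensus stays R)
  set.seed(42)
  n <- 100L
  nonCan <- sort(sample(n, 24L))
  res <- ifelse(seq_len(n) %in% nonCan, "C", "R")
  rmx <- cbind(res, rep("D", n))
  colnames(rmx) <- NULL
  seqs <- Biostrings::AAStringSet(setNames(paste0(res, "D"),
                                           sprintf("R%02d", 1:n)))
  fa <- new("FamilyAlignment", family = "OR", modelLength = 2L,
            members = data.frame(protein = sprintf("R%02d", 1:n),
                                 start = 1L, end = 2L),
            columnMaps = rep(list(1:2), n), residueMatrix = rmx,
            consensus = data.frame())
  fa <- computeConsensus(fa)
  status <- vapply(seq_len(n), function(i)
    canonicalCheck(seqs[i], fa, 1L, receptor = sprintf("R%02d", i))$status,
    "")
  expect_identical(which(status == "non_canonical"), nonCan)
  expect_equal(sum(status == "non_canonical"), 24L)
})

test_that("alignment FASTA round-trips through write and read", {
  cfg <- smallConfig(seed = 13L)
  prot <- generateProteome(cfg)
  fa <- prot@alignments[[1]]
  path <- withr::local_tempfile(fileext = ".afa")
  writeAlignmentFasta(fa, prot@proteins, path)
  back <- readFamilyAlignment(path, family = fa@family)
  expect_equal(back@modelLength, fa@modelLength)
  expect_equal(familyMembers(back), familyMembers(fa))
  expect_equal(back@columnMaps, fa@columnMaps,
               ignore_attr = TRUE)
  expect_equal(unname(back@residueMatrix), unname(fa@residueMatrix))
})

test_that("Stockholm alignments are read with the same conventions", {
  sto <- c("# STOCKHOLM 1.0",
           "P1/3-8  DR.YAKL",
           "P2/2-7  DRwY-KL",
           "P3/1-6  DR.FAKV",
           "//")
  path <- withr::local_tempfile(fileext = ".sto")
  writeLines(sto, path)
  fa <- readFamilyAlignment(path, family = "TOY", format = "stockholm")
  expect_equal(fa@modelLength, 6L)
  expect_equal(fa@columnMaps$P2, c(1L, 2L, NA, 3L, 5L, 6L))
  expect_equal(consensus(fa)$residue[2], "R")
})

test_that("variant VCF and TSV round-trip identically", {
  vs <- toyVariantSet()
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeVariantsVcf(vs, vcf)
  back <- readVariants(vcf, "vcf", cohort = cohort(vs))
  expect_equal(variantInfo(back), variantInfo(vs))
  expect_equal(genotypes(back), genotypes(vs))

  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeVariantsTsv(vs, tsv)
  back2 <- readVariants(tsv, "tsv", cohort = cohort(vs))
  expect_equal(variantInfo(back2), variantInfo(vs))
  expect_equal(genotypes(back2), genotypes(vs))
})

test_that("VCF genotype decoding and parse errors behave", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  hdr <- c("##fileformat=VCFv4.2",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", "S1", "S2", "S3"), collapse = "\t"))
  writeLines(c(hdr,
               paste(c("P1", "4", ".", "R", "H", ".", "PASS",
                       "CSQ=missense", "GT", "0|1", "1|1", "0|0"),
                     collapse = "\t")), vcf)
  vs <- readVariants(vcf, "vcf")
  expect_equal(unname(genotypes(vs)[1, ]), c(1L, 2L, 0L))

  writeLines(c(hdr,
               paste(c("P1", "4", ".", "R", "H", ".", "PASS",
                       "CSQ=weird", "GT", "0|1", "1|1", "0|0"),
                     collapse = "\t")), vcf)
  expect_error(readVariants(vcf, "vcf"), "unknown consequence")

  writeLines(c(hdr,
               paste(c("P1", "4", ".", "R", "H", ".", "PASS",
                       "CSQ=missense", "GT", "0|1|1", "1|1", "0|0"),
                     collapse = "\t")), vcf)
  expect_error(readVariants(vcf, "vcf"), "ploidy")
})

test_that("an empty VCF gives an empty variant set", {
  vs <- toyVariantSet()
  empty <- new("VariantSet",
               variants = variantInfo(vs)[0, ],
               geno = genotypes(vs)[0, , drop = FALSE],
               cohort = cohort(vs))
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeVariantsVcf(empty, vcf)
  back <- readVariants(vcf, "vcf", cohort = cohort(vs))
  expect_equal(nrow(variantInfo(back)), 0L)
})

test_that("generator mappings are recovered for written studies", {
  # round-trip: planted (family, column) assignments recovered by
  # mapVariantToColumn for all non-insertion variants
  cfg <- smallConfig(seed = 17L)
  prot <- generateProteome(cfg)
  vs <- generateVariants(prot, generateCohort(cfg), cfg)
  idx <- domainIndex(prot)
  v <- variantInfo(vs)
  for (r in sample(nrow(v), min(25, nrow(v)))) {
    hits <- mapVariantToColumn(v$protein[r], v$position[r], idx)
    # reconstruct truth from the generating alignment
    fam <- substr(v$protein[r], 1, 5)
    fa <- prot@alignments[[fam]]
    i <- match(v$protein[r], familyMembers(fa)$protein)
    st <- familyMembers(fa)$start[i]; en <- familyMembers(fa)$end[i]
    if (v$position[r] >= st && v$position[r] <= en) {
      col <- fa@columnMaps[[i]][v$position[r] - st + 1L]
      if (!is.na(col)) {
        expect_equal(hits$column, as.integer(col))
        expect_equal(hits$family, fam)
      } else {
        expect_equal(nrow(hits), 0L)
      }
    } else {
      expect_equal(nrow(hits), 0L)
    }
  }
})
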