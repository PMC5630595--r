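#' @include AllClasses.R
NULL

## ALT encoding for loss-of-function classes in the protein-space VCF.
.altEncode <- function(alt, consequence) {
  ifelse(consequence == "stop_gain", "<STOP>",
         ifelse(consequence == "frameshift", "<FS>", alt))
}
.altDecode <- function(alt, consequence) {
  ifelse(consequence == "stop_gain", "*",
         ifelse(consequence == "frameshift", "fs", alt))
}

#' Write a VariantSet as a minimal protein-space VCF
#'
#' A deliberately minimal VCF dialect: CHROM is the protein identifier,
#' POS the 1-based residue position, REF/ALT residue letters (symbolic
#' \code{<STOP>}/\code{<FS>} for loss-of-function classes), consequence in
#' INFO (\code{CSQ=}), and diploid GT per individual.
#'
#' @param vs a \linkS4class{VariantSet}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeVariantsVcf <- function(vs, path) {
  v <- vs@variants
  g <- vs@geno
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=CSQ,Number=1,Type=String,Description=\"Consequence class\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", colnames(g)), collapse = "\t"))
  gtCode <- c("0|0", "0|1", "1|1")
  lines <- vapply(seq_len(nrow(v)), function(i) {
    paste(c(v$protein[i], v$position[i], ".", v$ref[i],
            .altEncode(v$alt[i], v$consequence[i]), ".", "PASS",
            paste0("CSQ=", v$consequence[i]), "GT",
            gtCode[g[i, ] + 1L]), collapse = "\t")
  }, "")
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Write a VariantSet as TSV
#'
#' Header: protein, position, ref, alt, consequence, then one column per
#' individual holding the alternate-allele count (0/1/2).
#'
#' @inheritParams writeVariantsVcf
#' @return \code{path}, invisibly.
#' @export
writeVariantsTsv <- function(vs, path) {
  v <- vs@variants
  v$alt <- .altEncode(v$alt, v$consequence)
  tb <- cbind(v, as.data.frame(vs@geno, optional = TRUE))
  utils::write.table(tb, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

.decodeGT <- function(gt, where) {
  gt <- sub(":.*", "", gt)
  parts <- strsplit(gt, "[/|]")
  ok <- lengths(parts) == 2L
  if (!all(ok))
    stop("GT ploidy != 2 at ", where, ": ",
         paste(utils::head(gt[!ok], 3), collapse = ", "))
  al <- suppressWarnings(
    matrix(as.integer(unlist(parts)), ncol = 2L, byrow = TRUE))
  counts <- rowSums(al > 0L)
  counts[apply(is.na(al), 1L, any)] <- NA_integer_
  as.integer(counts)
}

#' Read a variant table (minimal VCF or TSV)
#'
#' Parses the formats written by \code{\link{writeVariantsVcf}} and
#' \code{\link{writeVariantsTsv}}, decoding genotypes to allele counts.
#' Unknown consequence strings and non-diploid genotypes are parse errors
#' reported with the offending row.
#'
#' @param path input file.
#' @param format "vcf" or "tsv".
#' @param cohort optional cohort data.frame (id, subpop, sex); built from
#'   the sample columns (subpop/sex NA) when absent.
#' @return a \linkS4class{VariantSet}.
#' @export
readVariants <- function(path, format = c("vcf", "tsv"), cohort = NULL) {
  format <- match.arg(format)
  if (format == "vcf") {
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    fx <- vcfR::getFIX(vcf)
    if (is.null(dim(fx))) fx <- t(as.matrix(fx))   # single-record case
    fx <- as.data.frame(fx, stringsAsFactors = FALSE)
    n <- nrow(fx)
    csq <- sub("^.*CSQ=([^;]+).*$", "\\1", vcfR::getINFO(vcf))
    if (n == 0L) {
      variants <- data.frame(protein = character(), position = integer(),
                             ref = character(), alt = character(),
                             consequence = character(),
                             stringsAsFactors = FALSE)
      ids <- colnames(vcf@gt)[-1]
      geno <- matrix(integer(0), 0L, length(ids),
                     dimnames = list(NULL, ids))
    } else {
      bad <- !(csq %in% c("missense", "stop_gain", "frameshift"))
      if (any(bad))
        stop("unknown consequence at VCF record(s) ",
             paste(utils::head(which(bad), 5), collapse = ", "))
      variants <- data.frame(
        protein = fx$CHROM, position = as.integer(fx$POS),
        ref = fx$REF, alt = .altDecode(fx$ALT, csq),
        consequence = csq, stringsAsFactors = FALSE)
      gt <- vcf@gt[, -1, drop = FALSE]
      if (n == 1L) gt <- matrix(gt, nrow = 1L,
                                dimnames = list(NULL, colnames(vcf@gt)[-1]))
      geno <- matrix(0L, n, ncol(gt), dimnames = list(NULL, colnames(gt)))
      for (i in seq_len(n))
        geno[i, ] <- .decodeGT(gt[i, ], paste0("record ", i))
    }
  } else {
    tb <- utils::read.delim(path, stringsAsFactors = FALSE,
                            check.names = FALSE)
    meta <- c("protein", "position", "ref", "alt", "consequence")
    if (!all(meta %in% names(tb)))
      stop("TSV must start with columns: ", paste(meta, collapse = ", "))
    bad <- !(tb$consequence %in% c("missense", "stop_gain", "frameshift"))
    if (any(bad))
      stop("unknown consequence at TSV row(s) ",
           paste(utils::head(which(bad), 5), collapse = ", "))
    variants <- tb[meta]
    variants$alt <- .altDecode(variants$alt, variants$consequence)
    variants$position <- as.integer(variants$position)
    gcols <- setdiff(names(tb), meta)
    geno <- as.matrix(tb[gcols])
    storage.mode(geno) <- "integer"
    rownames(geno) <- NULL
  }
  if (is.null(cohort))
    cohort <- data.frame(id = colnames(geno), subpop = NA_character_,
                         sex = NA_character_, stringsAsFactors = FALSE)
  methods::new("VariantSet", variants = variants, geno = geno,
               cohort = cohort)
}

#' Write one family alignment as aligned FASTA (A2M-style)
#'
#' Sequence names follow the profile convention \code{protein/start-end}.
#' Match columns are uppercase with "-" for gaps; insertion residues are
#' lowercase between the flanking match columns, so the residue-to-column
#' map can be reconstructed on read.
#'
#' @param fa a \linkS4class{FamilyAlignment}.
#' @param path output file.
#' @param proteins \link[Biostrings]{AAStringSet} holding member sequences.
#' @return \code{path}, invisibly.
#' @export
writeAlignmentFasta <- function(fa, proteins, path) {
  m <- fa@members
  lines <- character(0)
  for (i in seq_len(nrow(m))) {
    cm <- fa@columnMaps[[i]]
    seqChars <- strsplit(as.character(proteins[[m$protein[i]]]), "")[[1]]
    domRes <- seqChars[m$start[i]:m$end[i]]
    out <- character(0)
    nextCol <- 1L
    for (k in seq_along(cm)) {
      if (is.na(cm[k])) {
        out <- c(out, tolower(domRes[k]))
      } else {
        while (nextCol < cm[k]) { out <- c(out, "-"); nextCol <- nextCol + 1L }
        out <- c(out, toupper(domRes[k])); nextCol <- cm[k] + 1L
      }
    }
    while (nextCol <= fa@modelLength) { out <- c(out, "-"); nextCol <- nextCol + 1L }
    lines <- c(lines, sprintf(">%s/%d-%d", m$protein[i], m$start[i],
                              m$end[i]),
               paste(out, collapse = ""))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a family alignment from aligned FASTA or Stockholm
#'
#' Accepts the A2M-style FASTA written by \code{\link{writeAlignmentFasta}}
#' or a Stockholm alignment using the same conventions (uppercase match
#' columns, "-"/"." gaps, lowercase insertions, names
#' \code{protein/start-end}).
#'
#' @param path input file.
#' @param family family identifier (defaults to the file base name).
#' @param format "fasta" or "stockholm".
#' @return a \linkS4class{FamilyAlignment} with consensus computed.
#' @export
readFamilyAlignment <- function(path,
                                family = sub("\\.[^.]*$", "", basename(path)),
                                format = c("fasta", "stockholm")) {
  format <- match.arg(format)
  if (format == "fasta") {
    # BStringSet keeps residue case (insert states are lowercase)
    aln <- Biostrings::readBStringSet(path)
    seqs <- as.character(aln)
  } else {
    # parsed directly: the AA containers upper-case residues, which would
    # destroy the lowercase insert-state convention
    lines <- readLines(path)
    lines <- lines[!grepl("^#", lines) & !grepl("^//", lines) &
                   nzchar(trimws(lines))]
    nm <- sub("\\s.*$", "", lines)
    sq <- sub("^\\S+\\s+", "", lines)
    seqs <- vapply(split(sq, factor(nm, unique(nm))), paste0, "",
                   collapse = "")
  }
  nm <- names(seqs)
  prot <- sub("/.*$", "", nm)
  rng <- sub("^.*/", "", nm)
  start <- as.integer(sub("-.*$", "", rng))
  end <- as.integer(sub("^.*-", "", rng))
  if (any(is.na(start)) || any(is.na(end)))
    stop("sequence names must follow protein/start-end")
  L <- 0L
  parsed <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    ch <- strsplit(seqs[[i]], "")[[1]]
    cm <- integer(0)
    col <- 0L
    for (c0 in ch) {
      if (c0 == "-") {               # gap in a match column
        col <- col + 1L
      } else if (c0 == ".") {        # insert-state filler: not a column
        next
      } else if (c0 == toupper(c0)) {
        col <- col + 1L
        cm <- c(cm, col)
      } else {
        cm <- c(cm, NA_integer_)
      }
    }
    parsed[[i]] <- cm
    L <- max(L, col)
  }
  members <- data.frame(protein = prot, start = start, end = end,
                        stringsAsFactors = FALSE)
  residueMatrix <- matrix(NA_character_, length(seqs), L,
                          dimnames = list(prot, NULL))
  for (i in seq_along(seqs)) {
    ch <- strsplit(seqs[[i]], "")[[1]]
    ch <- ch[ch != "."]
    keep <- ch != "-" & ch == toupper(ch)
    cm <- parsed[[i]]
    residueMatrix[i, cm[!is.na(cm)]] <- toupper(ch[keep])
  }
  names(parsed) <- prot
  computeConsensus(methods::new("FamilyAlignment",
    family = family, modelLength = L, members = members,
    columnMaps = parsed, residueMatrix = residueMatrix,
    consensus = data.frame()))
}

#' Write every synthetic artifact of a study to a directory
#'
#' Writes the cohort TSV, variants (VCF and TSV), one aligned FASTA per
#' family, protein and coding FASTA, and the screen TSV.
#'
#' @param proteome a \linkS4class{Proteome}.
#' @param vs a \linkS4class{VariantSet}.
#' @param screen an \linkS4class{OdorScreen}.
#' @param dir output directory (created if needed).
#' @return character vector of the files written.
#' @export
writeStudy <- function(proteome, vs, screen, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(
    cohort = file.path(dir, "cohort.tsv"),
    vcf = file.path(dir, "variants.vcf"),
    tsv = file.path(dir, "variants.tsv"),
    proteins = file.path(dir, "proteins.fa"),
    cds = file.path(dir, "cds.fa"),
    screen = file.path(dir, "screen.tsv"))
  utils::write.table(vs@cohort, files["cohort"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeVariantsVcf(vs, files["vcf"])
  writeVariantsTsv(vs, files["tsv"])
  Biostrings::writeXStringSet(proteome@proteins, files["proteins"])
  Biostrings::writeXStringSet(proteome@cds, files["cds"])
  writeScreenTsv(screen, files["screen"])
  alnFiles <- vapply(proteome@alignments, function(fa) {
    p <- file.path(dir, paste0(fa@family, ".afa"))
    writeAlignmentFasta(fa, proteome@proteins, p)
    p
  }, "")
  c(files, alnFiles)
}

#' Write / read a receptor-odorant screen TSV
#'
#' Columns: receptor, odorant, log10_ec50 (NA for negative screens).
#'
#' @param screen an \linkS4class{OdorScreen}.
#' @param path file path.
#' @return \code{writeScreenTsv}: \code{path} invisibly;
#'   \code{readScreenTsv}: an \linkS4class{OdorScreen}.
#' @export
writeScreenTsv <- function(screen, path) {
  tb <- screen@table
  names(tb)[names(tb) == "log10Ec50"] <- "log10_ec50"
  utils::write.table(tb, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeScreenTsv
#' @export
readScreenTsv <- function(path) {
  tb <- utils::read.delim(path, stringsAsFactors = FALSE)
  names(tb)[names(tb) == "log10_ec50"] <- "log10Ec50"
  methods::new("OdorScreen", table = tb, canonical = logical(0))
}
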