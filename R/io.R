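# File-format boundaries. Internal coordinates are 1-based closed
# (IRanges idiom); BED half-open 0-based and VCF 1-based are converted
# here and only here.

#' Read and write reference genomes
#'
#' FASTA via Biostrings, with subgenome tags in a two-column sidecar TSV
#' (`chrom<TAB>subgenome`). Without a sidecar, tags default to the first
#' character of each chromosome name.
#'
#' @param fastaPath FASTA file
#' @param subgenomePath optional sidecar TSV
#' @return a [ReferenceGenome-class]
#' @export
readReferenceGenome <- function(fastaPath, subgenomePath = NULL) {
  seqs <- readDNAStringSet(fastaPath)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  sub <- NULL
  if (!is.null(subgenomePath)) {
    tab <- read.table(subgenomePath, sep = "\t", header = FALSE,
                      col.names = c("chrom", "subgenome"),
                      stringsAsFactors = FALSE)
    sub <- setNames(tab$subgenome, tab$chrom)
  }
  ReferenceGenome(seqs, sub)
}

#' @rdname readReferenceGenome
#' @param ref a [ReferenceGenome-class]
#' @export
writeReferenceGenome <- function(ref, fastaPath, subgenomePath = NULL) {
  writeXStringSet(refSequences(ref), fastaPath)
  if (!is.null(subgenomePath))
    write.table(data.frame(chrom = names(subgenomeTags(ref)),
                           subgenome = unname(subgenomeTags(ref))),
                subgenomePath, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  invisible(fastaPath)
}

#' Write a per-genotype variant set as VCF plus coverage BED
#'
#' Minimal single-sample VCF 4.2 with `GT:DP:AD` genotype fields;
#' coverage intervals go to a 0-based half-open BED.
#'
#' @param vs a [GenotypeVariantSet-class]
#' @param vcfPath,bedPath output paths
#' @export
writeGenotypeVCF <- function(vs, vcfPath, bedPath = NULL) {
  v <- vs@variants
  con <- file(vcfPath, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               paste0("##source=polyArray"),
               paste0("##platform=", vs@platform),
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
               "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
               "##FORMAT=<ID=AF,Number=1,Type=Float,Description=\"Alternate allele read fraction\">",
               paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", vs@genotype, sep = "\t")), con)
  if (nrow(v)) {
    altAD <- round(v$depth * v$altFrac)
    gt <- ifelse(v$altFrac > 0.8, "1/1", "0/1")
    writeLines(paste(v$chrom, v$pos, ".", v$ref, v$alt, ".", "PASS", ".",
                     "GT:DP:AD:AF",
                     paste0(gt, ":", v$depth, ":", v$depth - altAD, ",",
                            altAD, ":", sprintf("%.10g", v$altFrac)),
                     sep = "\t"), con)
  }
  if (!is.null(bedPath)) {
    cov <- vs@coverage
    write.table(data.frame(chrom = as.character(seqnames(cov)),
                           start = start(cov) - 1L, end = end(cov)),
                bedPath, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  invisible(vcfPath)
}

#' Read a per-genotype variant set from VCF plus coverage BED
#'
#' The alternate-allele read fraction is taken from the AD field (alt
#' depth over total AD) or, failing that, an AF field; depth from DP.
#' Without a BED, coverage defaults to the variant positions themselves.
#'
#' @param vcfPath single-sample VCF
#' @param bedPath optional coverage BED (0-based half-open)
#' @param genotype genotype id (default: the VCF sample name)
#' @param platform `"LONG_454"` or `"SHORT_ILLUMINA"`
#' @return a [GenotypeVariantSet-class]
#' @export
readGenotypeVCF <- function(vcfPath, bedPath = NULL, genotype = NULL,
                            platform = "SHORT_ILLUMINA") {
  vcf <- suppressWarnings(VariantAnnotation::readVcf(vcfPath, genome = "ref"))
  rr <- SummarizedExperiment::rowRanges(vcf)
  geno <- VariantAnnotation::geno(vcf)
  sample <- colnames(vcf)[1]
  dp <- as.numeric(geno$DP[, 1])
  if ("AF" %in% names(geno)) {       # exact fraction when provided
    altFrac <- as.numeric(geno$AF[, 1])
  } else if ("AD" %in% names(geno)) {
    ad <- geno$AD[, 1]
    altFrac <- vapply(ad, function(a)
      if (length(a) >= 2 && sum(a) > 0) a[2] / sum(a) else NA_real_,
      numeric(1))
  } else stop("VCF carries neither AD nor AF genotype fields")
  alt <- vapply(as.list(VariantAnnotation::alt(vcf)), function(a)
    as.character(a)[1], character(1))
  v <- data.frame(chrom = as.character(seqnames(rr)), pos = start(rr),
                  ref = as.character(VariantAnnotation::ref(vcf)),
                  alt = alt, depth = dp, altFrac = altFrac)
  cov <- if (!is.null(bedPath)) readCoverageBed(bedPath)
         else GRanges(v$chrom, IRanges(v$pos, width = 1))
  GenotypeVariantSet(genotype %||% sample, platform, v, cov)
}

#' Read a coverage BED file
#'
#' @param path BED path (0-based half-open; converted to 1-based closed)
#' @return a [GenomicRanges::GRanges]
#' @export
readCoverageBed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  GRanges(seqnames(gr), IRanges(start(gr), end(gr)))
}

#' Write and read the SNP summary matrix as TSV
#'
#' Fixed header `chrom pos ref alts <genotype columns> missing_frac
#' het_frac alt_freq`; genotype cells are encoded `.` (missing), `ref`,
#' `hom:<allele>` or `het:<allele>`. A `.gz` suffix triggers gzip
#' compression. Reading returns the table form (calls and panel
#' statistics), sufficient for the downstream filter steps.
#'
#' @param x a [SNPSummaryMatrix-class]
#' @param path output path (`.tsv` or `.tsv.gz`)
#' @export
writeSummaryMatrix <- function(x, path) {
  st <- siteStats(x)
  calls <- callMatrix(x)
  alts <- assay(x, "alt")
  enc <- matrix("ref", nrow(calls), ncol(calls),
                dimnames = dimnames(calls))
  enc[calls == "MISSING"] <- "."
  hom <- calls == "HOM_VARIANT"; het <- calls == "HET"
  enc[hom] <- paste0("hom:", alts[hom])
  enc[het] <- paste0("het:", alts[het])
  df <- cbind(st[, c("chrom", "pos", "ref", "alts")],
              as.data.frame(enc),
              missing_frac = st$missingFrac, het_frac = st$hetFrac,
              alt_freq = st$altFreq)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSummaryMatrix
#' @return `readSummaryMatrixTable`: a data.frame with one row per site
#' @export
readSummaryMatrixTable <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  read.table(con, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE)
}

#' Write and read intensity tables
#'
#' Long-format TSV `snp_id sample_id theta R` plus a sample sheet
#' `sample_id species`.
#'
#' @param x an [IntensityMatrix-class]
#' @param path intensity TSV path
#' @param sheetPath optional sample-sheet path
#' @export
writeIntensityTable <- function(x, path, sheetPath = NULL) {
  th <- thetaValues(x); rr <- signalR(x)
  df <- data.frame(snp_id = rep(rownames(th), ncol(th)),
                   sample_id = rep(colnames(th), each = nrow(th)),
                   theta = as.vector(th), R = as.vector(rr))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(sheetPath))
    write.table(data.frame(sample_id = colnames(th),
                           species = unname(sampleSpecies(x))),
                sheetPath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeIntensityTable
#' @export
readIntensityTable <- function(path, sheetPath = NULL) {
  df <- read.table(path, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE)
  if (all(c("X", "Y") %in% names(df))) {
    nz <- normalizeIntensity(df$X, df$Y)
    df$theta <- nz$theta; df$R <- nz$R
  }
  snps <- unique(df$snp_id); samples <- unique(df$sample_id)
  th <- matrix(NA_real_, length(snps), length(samples),
               dimnames = list(snps, samples))
  rr <- th
  i <- cbind(match(df$snp_id, snps), match(df$sample_id, samples))
  th[i] <- df$theta; rr[i] <- df$R
  species <- rep("NAPUS", length(samples))
  if (!is.null(sheetPath)) {
    sheet <- read.table(sheetPath, sep = "\t", header = TRUE,
                        stringsAsFactors = FALSE)
    species <- sheet$species[match(samples, sheet$sample_id)]
  }
  IntensityMatrix(theta = th, R = rr, species = setNames(species, samples))
}

#' Read marker-to-genome alignment hits
#'
#' Accepts a plain TSV (`marker chrom bp identity`), PSL (as produced by
#' BLAT; identity is matches over matches+mismatches) or PAF (identity is
#' residue matches over alignment block length).
#'
#' @param path input path
#' @param format `"tsv"`, `"psl"` or `"paf"`
#' @return data.frame `marker, chrom, bp, identity` suitable for
#'   [assignPhysical()]
#' @export
readAlignmentHits <- function(path, format = c("tsv", "psl", "paf")) {
  format <- match.arg(format)
  if (format == "tsv")
    return(read.table(path, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE))
  raw <- read.table(path, sep = "\t", header = FALSE, fill = TRUE,
                    stringsAsFactors = FALSE)
  if (format == "psl") {
    # skip optional header block
    firstNum <- suppressWarnings(!is.na(as.numeric(raw[[1]])))
    raw <- raw[firstNum, , drop = FALSE]
    data.frame(marker = raw[[10]], chrom = raw[[14]],
               bp = as.numeric(raw[[16]]) + 1,
               identity = 100 * as.numeric(raw[[1]]) /
                 (as.numeric(raw[[1]]) + as.numeric(raw[[2]])))
  } else {
    data.frame(marker = raw[[1]], chrom = raw[[6]],
               bp = as.numeric(raw[[8]]) + 1,
               identity = 100 * as.numeric(raw[[10]]) /
                 as.numeric(raw[[11]]))
  }
}

#' Read and write DH genotype matrices
#'
#' TSV with lines as rows and markers as columns; `A`/`B` calls, `-` or
#' empty for missing.
#'
#' @param path TSV path
#' @return character matrix with NA for missing calls
#' @export
readDHMatrix <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, row.names = 1,
                   stringsAsFactors = FALSE, check.names = FALSE)
  g <- as.matrix(df)
  g[g %in% c("-", "", ".")] <- NA_character_
  g
}

#' @rdname readDHMatrix
#' @param geno lines x markers character matrix
#' @export
writeDHMatrix <- function(geno, path) {
  out <- geno
  out[is.na(out)] <- "-"
  df <- data.frame(line = rownames(out) %||%
                     sprintf("L%03d", seq_len(nrow(out))), out,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
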