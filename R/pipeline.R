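# End-to-end array-design convenience wrapper, mainly used by the
# command-line interface and the determinism checks.

#' Run the full simulated design pipeline and write its outputs
#'
#' Simulates an allotetraploid reference and variant panel, aggregates the
#' panel, applies the filter cascade, extracts probes, counts their
#' genome-wide matches and selects assays. All outputs are written as
#' plain text so that two runs under the same seed can be compared
#' byte-for-byte.
#'
#' @param config a [simConfig()]
#' @param outdir output directory (created if needed)
#' @param thresholds a [filterThresholds()]
#' @param policy a [selectionPolicy()]
#' @return invisibly, a list with the in-memory results (`matrix`,
#'   `candidates`, `cascade`, `probes`, `selected`, `truth`) and `files`
#' @export
runDesignPipeline <- function(config, outdir,
                              thresholds = filterThresholds(),
                              policy = selectionPolicy()) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulateAllotetraploid(config)
  panel <- simulateVariantPanel(sim$reference, config)
  ssm <- aggregatePanel(panel$variantSets, sim$reference)
  cands <- annotateFlanks(ssm, sim$reference, thresholds$flankLength)
  cands <- addDesignScores(cands, panel$designScores)
  casc <- runCascade(cands, thresholds)
  pt <- probeTable(casc$survivors, sim$reference)
  counts <- snpMatchCounts(pt)
  counts <- merge(counts,
                  casc$survivors[, c("snpId", "chrom", "pos",
                                     "designScore")], by = "snpId")
  sel <- rankAndSelect(counts, policy)

  files <- c(reference = file.path(outdir, "reference.fa"),
             matrix = file.path(outdir, "matrix.tsv"),
             attrition = file.path(outdir, "attrition.csv"),
             survivors = file.path(outdir, "survivors.tsv"),
             probes = file.path(outdir, "probes.tsv"),
             selected = file.path(outdir, "selected.tsv"))
  writeReferenceGenome(sim$reference, files[["reference"]])
  writeSummaryMatrix(ssm, files[["matrix"]])
  write.csv(casc$report, files[["attrition"]], row.names = FALSE,
            quote = FALSE)
  write.table(casc$survivors, files[["survivors"]], sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(pt, files[["probes"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(sel, files[["selected"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(list(matrix = ssm, candidates = cands, cascade = casc,
                 probes = pt, selected = sel, truth = panel$truth,
                 files = files))
}
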