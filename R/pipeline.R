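# End-to-end pipeline stages on synthetic data. Every artifact is plain
# text, written deterministically (no timestamps, fixed number formatting),
# so a given seed yields a byte-identical output tree.

#' Write the synthetic input bundle
#'
#' Generates the full set of pipeline inputs (reference, peaks, coverage,
#' expression) and writes them in their standard on-disk formats.
#'
#' @param outDir output directory (created if needed).
#' @param config a \code{\link{SyntheticConfig}}.
#' @param withSequence write the genome FASTA.
#' @return invisibly, the list of generated objects.
#' @export
runSimulate <- function(outDir, config = SyntheticConfig(),
                        withSequence = TRUE) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    p <- function(...) file.path(outDir, ...)
    ref <- generateReference(config, withSequence = withSequence)
    pc <- generatePeaksAndCoverage(config, ref)
    writeChromSizes(ref$seqinfo, p("chrom.sizes"))
    if (!is.null(ref$genome))
        Biostrings::writeXStringSet(ref$genome, p("genome.fa"))
    writeGenesGtf(ref$genes, p("genes.gtf"))
    writeExpression(pc$expression, p("expression.tsv"))
    writePeaks(pc$h3k4me3, p("h3k4me3.narrowPeak"))
    writePeaks(pc$h3k27ac, p("h3k27ac.narrowPeak"))
    writeCoverageTrack(pc$ipK4, p("ip_h3k4me3.bedGraph"))
    writeCoverageTrack(pc$ipK27, p("ip_h3k27ac.bedGraph"))
    writeCoverageTrack(pc$input, p("input.bedGraph"))
    writeCoverageTrack(pc$ipK4rep1, p("ip_h3k4me3_rep1.bedGraph"))
    writeCoverageTrack(pc$ipK4rep2, p("ip_h3k4me3_rep2.bedGraph"))
    invisible(list(ref = ref, pc = pc))
}

#' Run the full pipeline on synthetic data
#'
#' Chains every stage on a seeded synthetic dataset: simulation, replicate
#' QC and peak filtering, element classification, broad-domain and
#' super-enhancer calling, cross-species conservation with chromatin-state
#' overlay, expression linkage and differential-expression filtering, and
#' core-regulatory-circuitry construction. All artifacts (BED/TSV/JSON,
#' including a machine-readable run manifest) are written under
#' \code{outDir}; identical seeds produce byte-identical trees.
#'
#' @param outDir output directory.
#' @param seed master seed (drives the config unless one is given).
#' @param config optional \code{\link{SyntheticConfig}} overriding the
#'   seed-derived default.
#' @param verbose log per-stage survivor counts via message().
#' @return invisibly, a list of the key computed results (counts, recovered
#'   conservation fractions, test statistics, CRC comparison).
#' @export
runDemo <- function(outDir, seed = 7L, config = NULL, verbose = TRUE) {
    if (is.null(config)) config <- SyntheticConfig(seed = as.integer(seed))
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    p <- function(...) file.path(outDir, ...)
    say <- function(...) if (verbose) message(sprintf(...))
    anno <- AnnotationConfig()
    rose <- RoseConfig()
    lift <- LiftOverConfig()
    counts <- list()

    ## --- simulate -------------------------------------------------------
    sim <- runSimulate(p("inputs"), config)
    ref <- sim$ref; pc <- sim$pc
    counts$peaks_h3k4me3_raw <- length(pc$h3k4me3)
    counts$peaks_h3k27ac_raw <- length(pc$h3k27ac)
    say("simulate: %d H3K4me3 and %d H3K27ac peaks on %d chromosomes",
        counts$peaks_h3k4me3_raw, counts$peaks_h3k27ac_raw, config@nChroms)

    ## --- qc -------------------------------------------------------------
    repCor <- replicateCorrelation(binCoverage(pc$ipK4rep1),
                                   binCoverage(pc$ipK4rep2))
    k4 <- filterPeaksByPvalue(pc$h3k4me3, "narrow")
    k27 <- filterPeaksByPvalue(pc$h3k27ac, "narrow")
    counts$peaks_h3k4me3_pvalue <- length(k4)
    counts$peaks_h3k27ac_pvalue <- length(k27)
    k4 <- enrichmentFilter(k4, pc$ipK4, pc$input)
    k27 <- enrichmentFilter(k27, pc$ipK27, pc$input)
    counts$peaks_h3k4me3_enriched <- length(k4)
    counts$peaks_h3k27ac_enriched <- length(k27)
    say("qc: replicate r = %.3f; H3K4me3 %d -> %d -> %d, H3K27ac %d -> %d -> %d (p-value, enrichment filters)",
        repCor, counts$peaks_h3k4me3_raw, counts$peaks_h3k4me3_pvalue,
        counts$peaks_h3k4me3_enriched, counts$peaks_h3k27ac_raw,
        counts$peaks_h3k27ac_pvalue, counts$peaks_h3k27ac_enriched)
    writeTsv(data.frame(
        metric = c("replicate_pearson_r",
                   "h3k4me3_raw", "h3k4me3_pvalue_pass",
                   "h3k4me3_enrichment_pass", "h3k27ac_raw",
                   "h3k27ac_pvalue_pass", "h3k27ac_enrichment_pass"),
        value = c(round(repCor, 6), counts$peaks_h3k4me3_raw,
                  counts$peaks_h3k4me3_pvalue,
                  counts$peaks_h3k4me3_enriched,
                  counts$peaks_h3k27ac_raw, counts$peaks_h3k27ac_pvalue,
                  counts$peaks_h3k27ac_enriched)), p("qc_report.tsv"))

    ## --- annotate -------------------------------------------------------
    elements <- classifyElements(k4, k27, ref$tss, anno)
    broad <- callBroadDomains(k4, ref$tss, anno)
    enhancers <- elements[elements$elementClass == "enhancer"]
    proms <- elements[elements$elementClass %in%
                      c("active_promoter", "poised_promoter")]
    counts$promoters <- length(proms)
    counts$active_promoters <- sum(elements$elementClass == "active_promoter")
    counts$poised_promoters <- sum(elements$elementClass == "poised_promoter")
    counts$enhancers <- length(enhancers)
    counts$unclassified_h3k27ac <-
        sum(elements$elementClass == "unclassified_h3k27ac")
    counts$broad_domains <- length(broad)
    say("annotate: %d promoters (%d active, %d poised), %d enhancers, %d broad domains, %d unclassified H3K27ac",
        counts$promoters, counts$active_promoters,
        counts$poised_promoters, counts$enhancers, counts$broad_domains,
        counts$unclassified_h3k27ac)
    writeElementsBed(proms, p("promoters.bed"))
    writeElementsBed(elements[elements$elementClass == "active_promoter"],
                     p("active_promoters.bed"))
    writeElementsBed(enhancers, p("enhancers.bed"))
    writeElementsBed(broad, p("broad_domains.bed"))
    writeElementsBed(elements[elements$elementClass ==
                              "unclassified_h3k27ac"],
                     p("unclassified_h3k27ac.bed"))
    writeTsv(elementCounts(elements, broad), p("element_counts.tsv"))
    writeElementsBed(rankTopEnhancers(enhancers, 3000L),
                     p("top_enhancers.bed"))

    ## --- standardize + second-pass enrichment ---------------------------
    stdEnh <- standardizeElements(enhancers, ref$seqinfo,
                                  anno@standardWidthBp)
    stdEnh <- enrichmentFilter(stdEnh, pc$ipK27, pc$input)
    counts$enhancers_standardized <- length(stdEnh)
    say("standardize: %d of %d enhancers pass the second-pass enrichment filter on 2 kb summit windows",
        counts$enhancers_standardized, counts$enhancers)

    ## --- super-enhancers ------------------------------------------------
    se <- callSuperEnhancers(enhancers, rose, pc$ipK27, pc$input)
    counts$stitched_regions <- length(se)
    counts$super_enhancers <- sum(se$isSuper)
    seGenes <- assignGenes(se[se$isSuper], ref$tss, rose@assignMode)
    typGenes <- assignGenes(se[!se$isSuper], ref$tss, rose@assignMode)
    say("superenhancer: %d stitched regions, %d super-enhancers (cutoff %.3f)",
        counts$stitched_regions, counts$super_enhancers,
        metadata(se)$cutoff)
    hockey <- data.frame(rank = rev(seq_along(se)),
                         signal = round(rev(se$signal), 6),
                         is_super = rev(se$isSuper))
    writeTsv(hockey, p("hockey.tsv"))
    seBed <- se
    seBed$elementClass <- ifelse(seBed$isSuper, "super_enhancer",
                                 "stitched_enhancer")
    seBed$rpmIP <- seBed$signal
    writeElementsBed(seBed, p("stitched.bed"))
    writeElementsBed(seBed[seBed$isSuper], p("superenhancers.bed"))
    writeTsv(data.frame(
        region = rep(seBed$name[seBed$isSuper], lengths(seGenes)),
        gene_id = unlist(seGenes)), p("se_genes.tsv"))

    ## --- conservation ---------------------------------------------------
    pair <- generateChainPair(config, ref, elements = stdEnh)
    writeChain(pair$chainSet, p("source_to_target.chain"))
    writeChromSizes(pair$targetSeqinfo, p("target.chrom.sizes"))
    writeElementsBed(pair$targetElements, p("target_elements.bed"))
    writeTsv(pair$orthology, p("orthology.tsv"))
    cons <- classifyConservation(stdEnh, pair$chainSet,
                                 pair$targetElements, lift)
    counts$conserved_functional <- sum(cons$status == "functional")
    counts$conserved_sequence_only <- sum(cons$status == "sequence_only")
    counts$un_conserved <- sum(cons$status == "un_conserved")
    recovered <- c(
        functional = counts$conserved_functional / nrow(cons),
        sequence_only = counts$conserved_sequence_only / nrow(cons))
    say("conserve: %d functional, %d sequence-only, %d un-conserved (planted fractions %.2f / %.2f, recovered %.3f / %.3f)",
        counts$conserved_functional, counts$conserved_sequence_only,
        counts$un_conserved, config@fracFunctional,
        config@fracSequenceOnly, recovered[1L], recovered[2L])
    writeTsv(cbind(cons[, c("name", "elementClass", "status", "reason",
                            "tName", "tStart", "tEnd", "tStrand")],
                   matchFrac = round(cons$matchFrac, 4),
                   matchedTarget = cons$matchedTarget),
             p("conservation.tsv"))

    dAll <- distanceToNearestGene(stdEnh, ref$tss)
    dFun <- dAll[cons$status == "functional"]
    dSeq <- dAll[cons$status == "sequence_only"]
    drawSize <- min(4000L, length(dAll))
    ks <- ksCompareWithRandomControl(dFun, dSeq, dAll, nDraws = 100L,
                                     drawSize = drawSize,
                                     seed = childSeed(config@seed, 707L))
    say("conserve: functional vs sequence-only distance KS D = %.3f, p = %.3g (control: 100 draws of %d)",
        ks$statistic, ks$p.value, drawSize)

    ## --- chromatin-state overlay ----------------------------------------
    seqOnly <- which(cons$status == "sequence_only")
    mapped <- GRanges(cons$tName[seqOnly],
                      IRanges(cons$tStart[seqOnly], cons$tEnd[seqOnly]))
    seqinfo(mapped) <- pair$targetSeqinfo
    states <- generateStateSegments(mapped, pair$targetSeqinfo,
                                    seed = config@seed)
    writeStateSegments(states$segments, p("target_states.bed"))
    ov <- overlayChromatinStates(mapped, states$segments,
                                 defaultStateCategoryMap())
    counts$seq_only_regulatory_any <- ov$nRegulatoryAny
    # k-means needs at most as many centres as distinct state patterns
    k <- min(100L, nrow(unique(ov$matrix)))
    clusters <- clusterStateMatrix(ov$matrix, k = k,
                                   seed = childSeed(config@seed, 808L))
    say("overlay: %d / %d sequence-only conserved enhancers regulatory in >= 1 tissue; k-means k = %d",
        ov$nRegulatoryAny, length(mapped), k)
    writeTsv(data.frame(element = cons$name[seqOnly], ov$matrix,
                        cluster = clusters,
                        regulatory_any = ov$regulatoryAny),
             p("state_matrix.tsv"))
    writeTsv(data.frame(tissue = names(ov$perTissue),
                        n_regulatory = as.integer(ov$perTissue)),
             p("state_per_tissue.tsv"))

    ## --- expression -----------------------------------------------------
    orth <- pair$orthology
    exprBoth <- cbind(source = pair$sourceExpression[orth$gene_source,
                                                     "rep1"],
                      target = pair$targetExpression[orth$gene_target,
                                                     "rep1"])
    rownames(exprBoth) <- orth$gene_source
    qn <- quantileNormalize(exprBoth)
    writeExpression(round(qn, 6), p("expression_quantile_normalized.tsv"))
    de <- applyDeThresholds(pair$deTable, computeFdr = TRUE)
    counts$deg_up <- unname(de$counts["up_in_A"])
    counts$deg_down <- unname(de$counts["down_in_A"])
    say("express: %d DEGs (%d up, %d down) of %d one2one orthologs",
        counts$deg_up + counts$deg_down, counts$deg_up, counts$deg_down,
        nrow(orth))
    writeTsv(cbind(de$records[, c("gene_id", "direction")],
                   log2_fold = round(de$records$log2_fold, 4),
                   pvalue = signif(de$records$pvalue, 4),
                   fdr = signif(de$records$fdr, 4)), p("de_genes.tsv"))
    flank <- tssFlankIntensity(ref$tss, pc$ipK4)
    writeTsv(data.frame(gene_id = names(flank),
                        h3k4me3_rpm_1kb = round(unname(flank), 6)),
             p("tss_flank_intensity.tsv"))

    tpm <- pc$expression[, "rep1"]
    activeGenes <- stats::na.omit(unique(k4$gene[
        countOverlaps(k4, k27, ignore.strand = TRUE) > 0L]))
    poisedGenes <- setdiff(stats::na.omit(unique(k4$gene)), activeGenes)
    wProm <- compareGroups(tpm[activeGenes], tpm[poisedGenes],
                           alternative = "greater")
    seLinked <- unique(unlist(seGenes))
    typLinked <- setdiff(unique(unlist(typGenes)), seLinked)
    wSe <- compareGroups(tpm[seLinked], tpm[typLinked],
                         alternative = "greater")
    say("express: active > poised promoter expression p = %.3g; SE-linked > typical-linked p = %.3g (one-sided Wilcoxon)",
        wProm$p.value, wSe$p.value)

    ## --- crc ------------------------------------------------------------
    crcScen <- generateCrcScenario(config@seed)
    crcs <- lapply(crcScen$species, function(sp) {
        cand <- candidateTFs(sp$candidates, sp$candidates, sp$tpm)
        buildCRC(cand, sp$constituentSeqs, crcScen$pwms)
    })
    cmp <- compareCRCs(crcs)
    counts$crc_shared_tfs <- cmp$nShared
    say("crc: %d TFs shared across %d species (pig-set ratio %.2f)",
        cmp$nShared, length(crcs),
        cmp$nShared / length(cmp$sets[[1L]]))
    writeTsv(data.frame(
        species = rep(names(cmp$sets), lengths(cmp$sets)),
        tf = unlist(cmp$sets),
        shared_all = unlist(cmp$sets) %in% cmp$shared),
        p("crc_members.tsv"))
    writeTsv(data.frame(metric = c("n_shared_all", "n_union",
                                   "frac_shared_all",
                                   "frac_shared_at_least2"),
                        value = c(cmp$nShared,
                                  length(unique(unlist(cmp$sets))),
                                  round(cmp$fracSharedAll, 4),
                                  round(cmp$fracSharedAtLeast2, 4))),
             p("crc_comparison.tsv"))

    ## --- manifest -------------------------------------------------------
    manifest <- list(
        tool = "CREconserve",
        seed = config@seed,
        parameters = list(
            nChroms = config@nChroms, chromLen = config@chromLen,
            nGenes = config@nGenes, nH3K4me3 = config@nH3K4me3,
            nH3K27ac = config@nH3K27ac,
            fracFunctional = config@fracFunctional,
            fracSequenceOnly = config@fracSequenceOnly,
            seTailExponent = config@seTailExponent,
            deEffectLog2 = config@deEffectLog2,
            noiseSd = config@noiseSd,
            narrowPvalueMax = 0.01, broadPvalueMax = 0.1,
            enrichmentFold = 2, enrichmentDiff = 1,
            tssUpstream = anno@upstreamBp, tssDownstream = anno@downstreamBp,
            broadMinWidth = anno@broadMinWidthBp,
            standardWidth = anno@standardWidthBp,
            stitchBp = rose@stitchBp, minMatch = lift@minMatch,
            deLog2Fold = 2, dePvalue = 0.001, deFdr = 0.01),
        counts = counts,
        statistics = list(
            replicate_pearson_r = round(repCor, 6),
            recovered_frac_functional = round(unname(recovered[1L]), 6),
            recovered_frac_sequence_only = round(unname(recovered[2L]), 6),
            ks_distance_D = round(ks$statistic, 6),
            ks_distance_p = signif(ks$p.value, 6),
            wilcoxon_active_vs_poised_p = signif(wProm$p.value, 6),
            wilcoxon_se_vs_typical_p = signif(wSe$p.value, 6)),
        files = sort(setdiff(list.files(outDir, recursive = TRUE),
                             "run_manifest.json")))
    jsonlite::write_json(manifest, p("run_manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = 10)
    invisible(list(config = config, counts = counts, repCor = repCor,
                   recovered = recovered, ks = ks, wilcoxProm = wProm,
                   wilcoxSe = wSe, crc = cmp, conservation = cons,
                   superEnhancers = se, manifest = manifest))
}
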