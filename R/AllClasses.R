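#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<- queryHits subjectHits
#' @importFrom IRanges IRanges
#' @importFrom GenomicRanges GRanges findOverlaps countOverlaps pintersect
#'   reduce resize seqnames start end width strand distance
#' @importFrom GenomeInfoDb Seqinfo seqlengths seqnames seqinfo seqinfo<-
#'   seqlevels keepSeqlevels
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' Configuration for the synthetic data generator
#'
#' Holds every knob of the seeded generator that emulates the pipeline's
#' inputs: genome and gene-annotation geometry, peak counts for the two
#' histone marks, the planted conservation fractions, the Pareto tail
#' exponent that shapes enhancer signal (and hence super-enhancer geometry),
#' the planted differential-expression effect and the coverage noise level.
#'
#' @slot seed integer master seed; all sub-generators derive child seeds from
#'   it by fixed offsets, so a given seed yields byte-identical outputs.
#' @slot nChroms,chromLen number of chromosomes and their common length (bp).
#' @slot nGenes number of non-overlapping genes to place.
#' @slot nH3K4me3,nH3K27ac peak counts for the two marks.
#' @slot fracFunctional,fracSequenceOnly planted fractions of elements that
#'   are functionally conserved / sequence-only conserved; the remainder is
#'   un-conserved. Must sum to at most 1.
#' @slot seTailExponent Pareto tail exponent of enhancer signal (alpha = 1.5
#'   by default gives a visible hockey-stick elbow).
#' @slot deEffectLog2 planted log2 expression effect for differential genes.
#' @slot noiseSd multiplicative coverage noise; 0 makes RPM recovery exact.
#' @slot fracK4AtTss fraction of H3K4me3 peaks placed inside TSS windows.
#' @slot fracK27Distal fraction of H3K27ac peaks placed TSS-distal (the
#'   enhancer-like population).
#' @export SyntheticConfig
#' @exportClass SyntheticConfig
SyntheticConfig <- setClass("SyntheticConfig",
    representation(
        seed = "integer",
        nChroms = "integer",
        chromLen = "integer",
        nGenes = "integer",
        nH3K4me3 = "integer",
        nH3K27ac = "integer",
        fracFunctional = "numeric",
        fracSequenceOnly = "numeric",
        seTailExponent = "numeric",
        deEffectLog2 = "numeric",
        noiseSd = "numeric",
        fracK4AtTss = "numeric",
        fracK27Distal = "numeric"),
    prototype(
        seed = 1L, nChroms = 2L, chromLen = 6500000L, nGenes = 200L,
        nH3K4me3 = 180L, nH3K27ac = 500L,
        fracFunctional = 0.30, fracSequenceOnly = 0.55,
        seTailExponent = 1.5, deEffectLog2 = 2, noiseSd = 0.1,
        fracK4AtTss = 0.9, fracK27Distal = 0.8))

setValidity("SyntheticConfig", function(object) {
    msg <- character()
    if (length(object@seed) != 1L || is.na(object@seed))
        msg <- c(msg, "seed must be a single integer")
    for (s in c("nChroms", "chromLen", "nH3K4me3", "nH3K27ac"))
        if (slot(object, s) < 1L)
            msg <- c(msg, paste0(s, " must be >= 1"))
    if (object@nGenes < 0L)
        msg <- c(msg, "nGenes must be >= 0")
    fr <- c(object@fracFunctional, object@fracSequenceOnly,
            object@fracK4AtTss, object@fracK27Distal)
    if (any(fr < 0) || any(fr > 1))
        msg <- c(msg, "fractions must lie in [0, 1]")
    if (object@fracFunctional + object@fracSequenceOnly > 1)
        msg <- c(msg, "fracFunctional + fracSequenceOnly must be <= 1")
    if (object@seTailExponent <= 0)
        msg <- c(msg, "seTailExponent must be positive")
    if (object@noiseSd < 0)
        msg <- c(msg, "noiseSd must be non-negative")
    if (length(msg)) msg else TRUE
})

#' Element-annotation window and width parameters
#'
#' TSS windows span \code{upstreamBp} upstream through \code{downstreamBp}
#' downstream of each transcription start site (strand-aware). H3K4me3 peaks
#' overlapping a TSS window and wider than \code{broadMinWidthBp} are broad
#' domains; \code{standardWidthBp} is the summit-centred standardized element
#' width used before conservation mapping.
#'
#' @export AnnotationConfig
#' @exportClass AnnotationConfig
AnnotationConfig <- setClass("AnnotationConfig",
    representation(
        upstreamBp = "integer",
        downstreamBp = "integer",
        broadMinWidthBp = "integer",
        standardWidthBp = "integer"),
    prototype(upstreamBp = 2500L, downstreamBp = 1500L,
              broadMinWidthBp = 4000L, standardWidthBp = 2000L))

setValidity("AnnotationConfig", function(object) {
    v <- c(object@upstreamBp, object@downstreamBp,
           object@broadMinWidthBp, object@standardWidthBp)
    if (any(v <= 0L)) "all window/width parameters must be > 0" else TRUE
})

#' ROSE-style super-enhancer calling parameters
#'
#' @slot stitchBp maximum gap (bp) across which neighbouring enhancers are
#'   stitched into one region (ROSE default 12,500).
#' @slot tssExclude if TRUE, drop enhancers overlapping TSS windows before
#'   stitching (off by default: elements reaching this stage are already
#'   TSS-depleted by the enhancer definition).
#' @slot assignMode gene-assignment rule: \code{"overlap_then_nearest"}
#'   (all TSS inside the stitched interval, else the single nearest) or
#'   \code{"nearest_tss"}.
#' @export RoseConfig
#' @exportClass RoseConfig
RoseConfig <- setClass("RoseConfig",
    representation(stitchBp = "integer", tssExclude = "logical",
                   assignMode = "character"),
    prototype(stitchBp = 12500L, tssExclude = FALSE,
              assignMode = "overlap_then_nearest"))

setValidity("RoseConfig", function(object) {
    msg <- character()
    if (object@stitchBp <= 0L) msg <- c(msg, "stitchBp must be > 0")
    if (!object@assignMode %in% c("overlap_then_nearest", "nearest_tss"))
        msg <- c(msg, "assignMode must be 'overlap_then_nearest' or 'nearest_tss'")
    if (length(msg)) msg else TRUE
})

#' Chain-mapping (liftOver-style) parameters
#'
#' @slot minMatch minimum fraction of an element's bases that must map
#'   through one chain for the element to count as mapped (default 0.2,
#'   the UCSC liftOver minMatch used for cross-species element conversion).
#' @slot allowMultiple if FALSE (default), an interval whose aligned bases
#'   split across more than one chain is reported unmapped.
#' @export LiftOverConfig
#' @exportClass LiftOverConfig
LiftOverConfig <- setClass("LiftOverConfig",
    representation(minMatch = "numeric", allowMultiple = "logical"),
    prototype(minMatch = 0.2, allowMultiple = FALSE))

setValidity("LiftOverConfig", function(object) {
    if (object@minMatch <= 0 || object@minMatch > 1)
        "minMatch must lie in (0, 1]" else TRUE
})

#' Read-coverage track with a declared library size
#'
#' A bedGraph-style coverage container: non-overlapping intervals whose
#' \code{score} is the number of reads assigned to the interval, plus the
#' total mapped-read count of the library the track came from. RPM values
#' are always computed against \code{totalReads} (carried in the track
#' header on disk), so they are well defined for sparse tracks.
#'
#' @slot cov GRanges with a numeric \code{score} column (reads per interval).
#' @slot totalReads total mapped reads used for RPM normalization.
#' @slot binSize nominal resolution (bp) the generator emitted the track at.
#' @export CoverageTrack
#' @exportClass CoverageTrack
CoverageTrack <- setClass("CoverageTrack",
    representation(cov = "GRanges", totalReads = "numeric",
                   binSize = "integer"),
    prototype(totalReads = 1e6, binSize = 10L))

setValidity("CoverageTrack", function(object) {
    msg <- character()
    if (is.null(object@cov$score))
        msg <- c(msg, "coverage GRanges needs a 'score' column")
    else if (any(object@cov$score < 0))
        msg <- c(msg, "coverage scores must be non-negative")
    if (length(object@totalReads) != 1L || object@totalReads <= 0)
        msg <- c(msg, "totalReads must be a single positive number")
    if (length(msg)) msg else TRUE
})

#' A set of pairwise-alignment chains between two genomes
#'
#' Each chain is a block-structured colinear alignment (UCSC chain model):
#' a header with score, source and target interval/strand, and an ordered
#' list of ungapped blocks separated by source/target gaps. Source strand is
#' always '+'; a '-' target strand stores target coordinates in
#' reverse-complement convention, exactly as in the UCSC chain format.
#' Internally each chain carries precomputed 0-based block coordinates on
#' both sides, which the minimum-match interval mapper consumes.
#'
#' @slot chains list of chain records (see \code{readChain}).
#' @slot sourceSeqinfo,targetSeqinfo Seqinfo for the two genomes.
#' @export ChainSet
#' @exportClass ChainSet
ChainSet <- setClass("ChainSet",
    representation(chains = "list", sourceSeqinfo = "Seqinfo",
                   targetSeqinfo = "Seqinfo"))

setValidity("ChainSet", function(object) {
    for (ch in object@chains) {
        v <- validateChainRecord(ch)
        if (!isTRUE(v)) return(v)
    }
    TRUE
})

# shared by the parser, the generator and the class validity
validateChainRecord <- function(ch) {
    need <- c("id", "score", "sName", "sSize", "sStart", "sEnd",
              "tName", "tSize", "tStrand", "tStart", "tEnd",
              "size", "dt", "dq")
    if (!all(need %in% names(ch)))
        return(sprintf("chain %s: missing fields",
                       if (is.null(ch$id)) "?" else ch$id))
    n <- length(ch$size)
    if (n < 1L || any(ch$size < 1L))
        return(sprintf("chain %s: block sizes must be >= 1", ch$id))
    if (length(ch$dt) != n - 1L || length(ch$dq) != n - 1L)
        return(sprintf("chain %s: need exactly n-1 gap entries", ch$id))
    if (sum(ch$size) + sum(ch$dt) != ch$sEnd - ch$sStart)
        return(sprintf("chain %s: source block/gap sum mismatch", ch$id))
    if (sum(ch$size) + sum(ch$dq) != ch$tEnd - ch$tStart)
        return(sprintf("chain %s: target block/gap sum mismatch", ch$id))
    if (any(ch$dt < 0L) || any(ch$dq < 0L))
        return(sprintf("chain %s: negative gap", ch$id))
    TRUE
}

setMethod("show", "SyntheticConfig", function(object) {
    cat("SyntheticConfig (seed ", object@seed, ")\n", sep = "")
    cat("  genome: ", object@nChroms, " x ", object@chromLen, " bp, ",
        object@nGenes, " genes\n", sep = "")
    cat("  peaks:  ", object@nH3K4me3, " H3K4me3, ", object@nH3K27ac,
        " H3K27ac (Pareto alpha ", object@seTailExponent, ")\n", sep = "")
    cat("  planted conservation: functional ", object@fracFunctional,
        ", sequence-only ", object@fracSequenceOnly, "\n", sep = "")
})

setMethod("show", "CoverageTrack", function(object) {
    cat("CoverageTrack: ", length(object@cov), " intervals, ",
        "totalReads ", format(object@totalReads, big.mark = ","),
        ", bin ", object@binSize, " bp\n", sep = "")
})

setMethod("show", "ChainSet", function(object) {
    nrev <- sum(vapply(object@chains, function(ch) ch$tStrand == "-",
                       logical(1)))
    cat("ChainSet: ", length(object@chains), " chains (",
        nrev, " reverse-strand)\n", sep = "")
})

#' @describeIn CoverageTrack total mapped reads of the library
#' @param object a CoverageTrack
#' @export
setGeneric("totalReads", function(object) standardGeneric("totalReads"))
setMethod("totalReads", "CoverageTrack", function(object) object@totalReads)

#' @describeIn CoverageTrack the coverage intervals as a GRanges
#' @export
setGeneric("coverageRanges", function(object) standardGeneric("coverageRanges"))
setMethod("coverageRanges", "CoverageTrack", function(object) object@cov)

#' @describeIn ChainSet list of chain records
#' @param object a ChainSet
#' @export
setGeneric("chains", function(object) standardGeneric("chains"))
setMethod("chains", "ChainSet", function(object) object@chains)
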