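## One-shot orchestration of the curation workflow:
## ORFs -> classification -> merging -> normalization -> reports.

#' Run the full curation workflow
#'
#' Executes ORF extraction, evidence-based classification, anchor-based
#' merge detection and count normalization, writes the complete report
#' bundle (see [writeReports()]) plus a run summary, and returns the
#' intermediate objects. Identical inputs give byte-identical reports.
#'
#' @param transcripts A [TranscriptSet-class].
#' @param hits Homology-hit \code{data.frame} over the transcripts' ORFs.
#' @param counts Optional raw-count \code{data.frame}
#'   (\code{transcript_id}, \code{raw}); taken from the transcript set's
#'   own counts when \code{NULL} and available.
#' @param outDir Output directory for the report bundle (\code{NULL} to
#'   skip writing).
#' @param thresholds A [curationThresholds()] list.
#' @param mergeSpace Anchor space for [findMergePairs()].
#' @param anchorLengths Anchor-length range.
#' @param k Top ORFs per transcript.
#' @return List with \code{orfs}, \code{classification},
#'   \code{mergePairs}, \code{normCounts}, \code{summary} (class tallies,
#'   merge-pair count, chimera count) and \code{files} (paths written, or
#'   \code{NULL}).
#' @export
runPipeline <- function(transcripts, hits, counts = NULL, outDir = NULL,
                        thresholds = curationThresholds(),
                        mergeSpace = "protein", anchorLengths = 5:15,
                        k = 3L) {
    orfs <- findOrfs(transcripts)
    classification <- classifyTranscripts(transcripts, hits, orfs = orfs,
                                          thresholds = thresholds, k = k)
    mergePairs <- findMergePairs(transcripts, space = mergeSpace,
                                 lengths = anchorLengths)
    if (is.null(counts)) {
        rc <- rawCounts(transcripts)
        if (any(!is.na(rc)))
            counts <- data.frame(transcript_id = names(rc),
                                 raw = unname(rc),
                                 stringsAsFactors = FALSE)[!is.na(rc), ]
    }
    normCounts <- if (!is.null(counts))
        normalizeCounts(counts, transcripts) else NULL
    files <- if (!is.null(outDir))
        writeReports(classification, outDir, mergePairs = mergePairs,
                     normCounts = normCounts) else NULL
    summary <- list(n_transcripts = length(transcripts),
                    class_counts = classCounts(classification),
                    n_merge_pairs = nrow(mergePairs),
                    n_chimera_candidates = sum(
                        transcriptClasses(classification)$chimera_candidate))
    list(orfs = orfs, classification = classification,
         mergePairs = mergePairs, normCounts = normCounts,
         summary = summary, files = files)
}
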