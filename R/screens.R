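## Secondary homology screens. Both consume externally produced hit tables
## (any search engine emitting the 12/13-column tabular format); neither
## bundles a database.

#' Screen unannotated transcripts against a noncoding-RNA set
#'
#' Given the ids of transcripts with no protein-level match and a
#' nucleotide-space hit table of those transcripts against an ncRNA
#' reference set, returns one verdict per queried id: \code{match} when its
#' best hit falls strictly below the threshold, otherwise \code{no-match}.
#' Hits for ids outside the queried set are ignored with a warning.
#'
#' @param noHitIds Character vector of unannotated transcript ids.
#' @param hits Hit \code{data.frame} (see [readHits()]).
#' @param threshold E-value threshold (default \code{1e-12}; the screen is
#'   intentionally stringent and configurable).
#' @return \code{data.frame}: \code{query_id}, \code{subject_id},
#'   \code{evalue}, \code{verdict}; exactly one row per queried id.
#' @export
screenNcrna <- function(noHitIds, hits, threshold = 1e-12) {
    stray <- setdiff(unique(hits$qseqid), noHitIds)
    if (length(stray)) {
        warning("ignoring hits for ids outside the no-hit set: ",
                paste(stray, collapse = ", "))
        hits <- hits[hits$qseqid %in% noHitIds, , drop = FALSE]
    }
    best <- bestHitPerOrf(hits)
    m <- match(noHitIds, best$qseqid)
    ev <- best$evalue[m]
    data.frame(query_id = noHitIds,
               subject_id = best$sseqid[m],
               evalue = ev,
               verdict = ifelse(!is.na(ev) & ev < threshold,
                                "match", "no-match"),
               stringsAsFactors = FALSE)
}

#' Check annotated genes for presence in a reference proteome
#'
#' For each annotated transcript, reports the best subject and E-value of a
#' search of its representative ORF against a reference proteome, and
#' whether the match is significant (strictly below the threshold).
#'
#' @param annotations Annotation \code{data.frame} with a
#'   \code{transcript_id} column (e.g. from [annotationRecords()]), or a
#'   character vector of query ids.
#' @param hits Hit \code{data.frame} of the representative ORFs (or
#'   transcripts) against the proteome; query ids must equal the
#'   transcript ids.
#' @param threshold Significance threshold (default \code{1e-5}).
#' @return \code{data.frame}: \code{query_id}, \code{best_subject},
#'   \code{evalue}, \code{significant}; one row per query.
#' @export
screenProteome <- function(annotations, hits, threshold = 1e-5) {
    ids <- if (is.character(annotations)) unique(annotations) else
        unique(annotations$transcript_id)
    best <- bestHitPerOrf(hits[hits$qseqid %in% ids, , drop = FALSE])
    m <- match(ids, best$qseqid)
    ev <- best$evalue[m]
    data.frame(query_id = ids,
               best_subject = best$sseqid[m],
               evalue = ev,
               significant = !is.na(ev) & ev < threshold,
               stringsAsFactors = FALSE)
}
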