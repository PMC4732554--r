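#' @import methods
#' @importFrom Biostrings DNAStringSet AAStringSet DNAString AAString
#'   readDNAStringSet writeXStringSet reverseComplement subseq
#'   pairwiseAlignment pid letterFrequency GENETIC_CODE width
#' @importFrom S4Vectors DataFrame
#' @importFrom stats setNames runif rlnorm
#' @importFrom utils read.delim write.table head
NULL

## Recognised partition classes, in precedence order.
TX_CLASSES <- c("LONG_REPEAT", "BROKEN_ORF_ERROR", "MULTI_GENE",
                "UNIQUE_HIGH", "UNIQUE_LOW", "NO_HIT")

#' TranscriptSet: assembled transcripts with optional raw counts
#'
#' A thin container around a named \link[Biostrings]{DNAStringSet} holding
#' assembled transcripts (Trinity-style identifiers such as
#' \code{C55368_G1_I3}) and, optionally, one raw read count per transcript.
#'
#' @slot sequences A named \code{DNAStringSet}; names are transcript ids,
#'   unique and non-empty. Sequences are stored uppercased; IUPAC ambiguity
#'   codes are permitted.
#' @slot counts Numeric vector parallel to \code{sequences}; \code{NA} where
#'   no count is known, otherwise \code{>= 0}.
#'
#' @seealso [TranscriptSet()], [readTranscripts()]
#' @exportClass TranscriptSet
setClass("TranscriptSet",
         slots = c(sequences = "DNAStringSet", counts = "numeric"))

setValidity("TranscriptSet", function(object) {
    ids <- names(object@sequences)
    if (length(object@sequences) > 0L &&
        (is.null(ids) || any(!nzchar(ids))))
        return("all transcripts must have non-empty ids")
    if (anyDuplicated(ids))
        return(paste0("duplicate transcript ids: ",
                      paste(unique(ids[duplicated(ids)]), collapse = ", ")))
    if (length(object@sequences) > 0L && any(width(object@sequences) < 1L))
        return("zero-length transcript sequence")
    if (length(object@counts) != length(object@sequences))
        return("counts must be parallel to sequences")
    if (any(!is.na(object@counts) & object@counts < 0))
        return("raw counts must be non-negative")
    TRUE
})

#' Construct a TranscriptSet
#'
#' @param sequences A named character vector or named \code{DNAStringSet} of
#'   transcript sequences. Lowercase letters are uppercased.
#' @param counts Optional numeric vector of raw counts, either parallel to
#'   \code{sequences} or named by transcript id. Missing ids get \code{NA}.
#' @return A [TranscriptSet-class] object.
#' @examples
#' ts <- TranscriptSet(c(t1 = "ATGGCCTAA", t2 = "ACGTACGTACGT"),
#'                     counts = c(t1 = 10, t2 = 0))
#' length(ts)
#' transcriptIds(ts)
#' @export
TranscriptSet <- function(sequences, counts = NULL) {
    if (is.character(sequences)) {
        nm <- names(sequences)
        sequences <- DNAStringSet(toupper(sequences))
        names(sequences) <- nm
    } else {
        sequences <- DNAStringSet(toupper(as.character(sequences)))
    }
    cts <- rep(NA_real_, length(sequences))
    if (!is.null(counts)) {
        if (!is.null(names(counts))) {
            idx <- match(names(sequences), names(counts))
            cts <- as.numeric(counts)[idx]
        } else {
            stopifnot(length(counts) == length(sequences))
            cts <- as.numeric(counts)
        }
    }
    new("TranscriptSet", sequences = sequences, counts = cts)
}

#' @describeIn TranscriptSet Number of transcripts.
#' @param x A \code{TranscriptSet}.
#' @export
setMethod("length", "TranscriptSet", function(x) length(x@sequences))

#' @export
setMethod("names", "TranscriptSet", function(x) names(x@sequences))

#' @export
setMethod("[", "TranscriptSet", function(x, i, j, ..., drop = TRUE) {
    if (is.character(i)) i <- match(i, names(x@sequences))
    new("TranscriptSet", sequences = x@sequences[i], counts = x@counts[i])
})

setGeneric("transcriptIds", function(x) standardGeneric("transcriptIds"))
#' Transcript identifiers
#' @param x A [TranscriptSet-class] or [OrfSet-class].
#' @return Character vector of transcript ids.
#' @export
setMethod("transcriptIds", "TranscriptSet", function(x) names(x@sequences))

setGeneric("transcriptSeqs", function(x) standardGeneric("transcriptSeqs"))
#' Underlying transcript sequences
#' @param x A [TranscriptSet-class].
#' @return The named \code{DNAStringSet}.
#' @export
setMethod("transcriptSeqs", "TranscriptSet", function(x) x@sequences)

setGeneric("rawCounts", function(x) standardGeneric("rawCounts"))
#' Raw read counts
#' @param x A [TranscriptSet-class].
#' @return Named numeric vector of raw counts (\code{NA} where unknown).
#' @export
setMethod("rawCounts", "TranscriptSet",
          function(x) setNames(x@counts, names(x@sequences)))

setGeneric("rawCounts<-", function(x, value) standardGeneric("rawCounts<-"))
#' @export
setReplaceMethod("rawCounts", "TranscriptSet", function(x, value) {
    if (!is.null(names(value)))
        value <- as.numeric(value)[match(names(x@sequences), names(value))]
    x@counts <- as.numeric(value)
    validObject(x)
    x
})

setMethod("show", "TranscriptSet", function(object) {
    cat("TranscriptSet with", length(object), "transcripts\n")
    if (length(object)) {
        w <- width(object@sequences)
        cat("  width: ", min(w), "..", max(w), " nt; ",
            sum(!is.na(object@counts)), " with raw counts\n", sep = "")
        cat("  ids: ", paste(head(names(object@sequences), 3L),
                             collapse = ", "),
            if (length(object) > 3L) ", ..." else "", "\n", sep = "")
    }
})

#' OrfSet: open reading frames of one or more transcripts
#'
#' Stop-to-stop open reading frames found by [findOrfs()]. Coordinates
#' (\code{nt_start}, \code{nt_end}, 1-based inclusive) always refer to the
#' forward axis of the source transcript, also for reverse-strand ORFs.
#'
#' @slot table A \code{data.frame} with columns \code{orf_id},
#'   \code{transcript_id}, \code{strand} ("forward"/"reverse"), \code{frame}
#'   (1..3 on the reading strand), \code{nt_start}, \code{nt_end},
#'   \code{aa} (translation, no stop symbol), \code{aa_length}, and
#'   \code{ordinal} (deterministic scan order within the transcript).
#' @exportClass OrfSet
setClass("OrfSet", slots = c(table = "data.frame"))

.ORF_COLS <- c("orf_id", "transcript_id", "strand", "frame",
               "nt_start", "nt_end", "aa", "aa_length", "ordinal")

setValidity("OrfSet", function(object) {
    tb <- object@table
    if (!all(.ORF_COLS %in% names(tb)))
        return(paste("missing ORF columns:",
                     paste(setdiff(.ORF_COLS, names(tb)), collapse = ", ")))
    if (nrow(tb) == 0L) return(TRUE)
    if (any(grepl("*", tb$aa, fixed = TRUE)))
        return("ORF translation contains a stop symbol")
    if (any(nchar(tb$aa) != tb$aa_length))
        return("aa_length inconsistent with aa sequence")
    if (any(tb$nt_end - tb$nt_start + 1L != 3L * tb$aa_length))
        return("nucleotide span must be 3 x aa_length")
    if (!all(tb$strand %in% c("forward", "reverse")))
        return("strand must be 'forward' or 'reverse'")
    if (!all(tb$frame %in% 1:3))
        return("frame must be in 1..3")
    TRUE
})

OrfSet <- function(table) {
    if (nrow(table)) rownames(table) <- NULL
    new("OrfSet", table = table)
}

setGeneric("orfTable", function(x) standardGeneric("orfTable"))
#' ORF table
#' @param x An [OrfSet-class].
#' @return The underlying \code{data.frame} (one row per ORF).
#' @export
setMethod("orfTable", "OrfSet", function(x) x@table)

#' @export
setMethod("transcriptIds", "OrfSet",
          function(x) unique(x@table$transcript_id))

#' @export
setMethod("length", "OrfSet", function(x) nrow(x@table))

#' @export
setMethod("as.data.frame", "OrfSet",
          function(x, row.names = NULL, optional = FALSE, ...) x@table)

setGeneric("aaSequences", function(x) standardGeneric("aaSequences"))
#' ORF protein sequences
#' @param x An [OrfSet-class].
#' @return A named \code{AAStringSet} (names are ORF ids).
#' @export
setMethod("aaSequences", "OrfSet", function(x) {
    if (nrow(x@table) == 0L) return(AAStringSet())
    setNames(AAStringSet(x@table$aa), x@table$orf_id)
})

setMethod("show", "OrfSet", function(object) {
    tb <- object@table
    cat("OrfSet with", nrow(tb), "ORFs from",
        length(unique(tb$transcript_id)), "transcripts\n")
    if (nrow(tb))
        cat("  aa length: ", min(tb$aa_length), "..", max(tb$aa_length),
            "; ", sum(tb$strand == "reverse"), " on reverse strand\n",
            sep = "")
})

#' ClassificationResult: partitioned transcriptome
#'
#' Result of [classifyTranscripts()]: one partition class per transcript plus
#' the annotation records supporting it.
#'
#' @slot classes \code{data.frame} with one row per transcript: columns
#'   \code{transcript_id}, \code{class} (one of \code{LONG_REPEAT},
#'   \code{BROKEN_ORF_ERROR}, \code{MULTI_GENE}, \code{UNIQUE_HIGH},
#'   \code{UNIQUE_LOW}, \code{NO_HIT}), \code{chimera_candidate},
#'   \code{breakpoint_subject}, \code{breakpoint_start}, \code{breakpoint_end}.
#' @slot annotations \code{data.frame} of annotation records: columns
#'   \code{transcript_id}, \code{orf_id}, \code{subject_accession},
#'   \code{subject_title}, \code{evalue}, \code{bitscore}, \code{strand}.
#' @exportClass ClassificationResult
setClass("ClassificationResult",
         slots = c(classes = "data.frame", annotations = "data.frame"))

setValidity("ClassificationResult", function(object) {
    cl <- object@classes
    if (!all(c("transcript_id", "class", "chimera_candidate") %in% names(cl)))
        return("classes table lacks required columns")
    if (anyDuplicated(cl$transcript_id))
        return("a transcript may carry exactly one class")
    if (nrow(cl) && !all(cl$class %in% TX_CLASSES))
        return("unknown partition class")
    bad <- cl$chimera_candidate & cl$class != "MULTI_GENE"
    if (any(bad))
        return("chimera_candidate only allowed for MULTI_GENE")
    noh <- cl$transcript_id[cl$class == "NO_HIT"]
    if (any(object@annotations$transcript_id %in% noh))
        return("NO_HIT transcripts cannot carry annotations")
    TRUE
})

setGeneric("transcriptClasses", function(x) standardGeneric("transcriptClasses"))
#' Per-transcript partition classes
#' @param x A [ClassificationResult-class].
#' @return \code{data.frame}, one row per transcript.
#' @export
setMethod("transcriptClasses", "ClassificationResult",
          function(x) x@classes)

setGeneric("annotationRecords", function(x) standardGeneric("annotationRecords"))
#' Annotation records backing the classification
#' @param x A [ClassificationResult-class].
#' @return \code{data.frame} of annotation records.
#' @export
setMethod("annotationRecords", "ClassificationResult",
          function(x) x@annotations)

setGeneric("classCounts", function(x) standardGeneric("classCounts"))
#' Tally of transcripts per partition class
#' @param x A [ClassificationResult-class].
#' @return Named integer vector over all six classes.
#' @export
setMethod("classCounts", "ClassificationResult", function(x) {
    tab <- table(factor(x@classes$class, levels = TX_CLASSES))
    setNames(as.integer(tab), names(tab))
})

setMethod("show", "ClassificationResult", function(object) {
    cat("ClassificationResult over", nrow(object@classes), "transcripts\n")
    cc <- classCounts(object)
    for (k in names(cc)) cat(sprintf("  %-17s %d\n", k, cc[[k]]))
    cat("  chimera candidates:",
        sum(object@classes$chimera_candidate), "\n")
})
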