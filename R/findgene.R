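## Iterative gene-family expansion over transcript-derived proteins.
##
## From a seed protein, admit database proteins passing an identity cutoff
## and a length-difference cutoff, then query each admitted member exactly
## once until no new member is added (breadth-style fixed point). The
## default homology backend is a deterministic global aligner; any search
## engine returning (id, identity, length difference) per query can be
## plugged in instead.

#' Global pairwise identity between two proteins
#'
#' Deterministic Needleman-Wunsch global alignment (BLOSUM62, gap opening
#' 10, gap extension 0.5). Identity is matched positions over aligned
#' columns (gaps included in the denominator).
#'
#' @param a,b Protein strings.
#' @param substitutionMatrix,gapOpening,gapExtension Alignment scoring;
#'   fixed defaults keep results reproducible.
#' @return Named numeric vector: \code{identity} (percent) and
#'   \code{length_difference} (absolute residue difference).
#' @examples
#' pairwiseIdentity("AAAA", "AAAT")  # identity 75
#' @export
pairwiseIdentity <- function(a, b, substitutionMatrix = "BLOSUM62",
                             gapOpening = 10, gapExtension = 0.5) {
    stopifnot(nzchar(a), nzchar(b))
    aln <- pairwiseAlignment(AAString(a), AAString(b), type = "global",
                             substitutionMatrix = substitutionMatrix,
                             gapOpening = gapOpening,
                             gapExtension = gapExtension)
    c(identity = pid(aln, type = "PID1"),
      length_difference = abs(nchar(a) - nchar(b)))
}

## Default backend: align the query against every database protein,
## prefiltering on the (cheap) length criterion.
.alignmentBackend <- function(db) {
    lens <- nchar(db)
    function(query, maxLenDiff) {
        cand <- names(db)[abs(lens - nchar(query)) <= maxLenDiff]
        if (length(cand) == 0L)
            return(data.frame(id = character(), identity = numeric(),
                              length_difference = numeric(),
                              stringsAsFactors = FALSE))
        res <- t(vapply(cand, function(id)
            pairwiseIdentity(query, db[[id]]), numeric(2L)))
        data.frame(id = cand, identity = res[, 1L],
                   length_difference = res[, 2L],
                   stringsAsFactors = FALSE, row.names = NULL)
    }
}

#' Derive the representative protein per transcript
#'
#' The longest ORF's translation represents each transcript in the
#' gene-family search database.
#'
#' @param transcripts A [TranscriptSet-class].
#' @param minAa Minimum ORF size in residues.
#' @return Named character vector (transcript id -> protein).
#' @export
representativeProteins <- function(transcripts, minAa = 10L) {
    tb <- orfTable(topOrfs(findOrfs(transcripts, minAa = minAa), k = 1L))
    setNames(tb$aa, tb$transcript_id)
}

#' Iteratively expand a gene family from a seed protein
#'
#' Queries the seed against the protein database, admits hits with identity
#' strictly above \code{identityCutoff} percent and absolute length
#' difference strictly below \code{lengthCutoff} (residues by default, or
#' percent of the query length), then queries each admitted member exactly
#' once, terminating when an iteration adds no new member. The seed itself
#' is excluded from the result.
#'
#' @param seed Seed protein string (possibly from another organism).
#' @param db Named character vector of proteins (id -> sequence), e.g. from
#'   [representativeProteins()].
#' @param identityCutoff Percent identity cutoff (default 40).
#' @param lengthCutoff Length-difference cutoff (default 50).
#' @param lengthMode \code{"absolute"} residues (default) or
#'   \code{"percent"} of the query length.
#' @param backend Optional search function \code{(query, maxLenDiff) ->
#'   data.frame(id, identity, length_difference)}; defaults to the internal
#'   global aligner.
#' @return List with \code{members} (character ids), \code{evidence}
#'   (\code{data.frame}: member, parent, identity, length_difference) and
#'   \code{iterations} (number of expansion waves run).
#' @export
findGeneFamily <- function(seed, db, identityCutoff = 40,
                           lengthCutoff = 50,
                           lengthMode = c("absolute", "percent"),
                           backend = NULL) {
    lengthMode <- match.arg(lengthMode)
    stopifnot(length(db) > 0L, identityCutoff > 0, identityCutoff <= 100,
              lengthCutoff > 0)
    if (is.null(backend)) backend <- .alignmentBackend(db)
    seqOf <- function(id) if (id == ".seed") seed else db[[id]]
    members <- character()
    evidence <- data.frame(member = character(), parent = character(),
                           identity = numeric(),
                           length_difference = numeric(),
                           stringsAsFactors = FALSE)
    queue <- ".seed"
    processed <- character()
    iterations <- 0L
    while (length(queue)) {
        iterations <- iterations + 1L
        nextQueue <- character()
        for (q in queue) {
            if (q %in% processed) next
            processed <- c(processed, q)
            qseq <- seqOf(q)
            maxDiff <- if (lengthMode == "absolute") lengthCutoff else
                lengthCutoff / 100 * nchar(qseq)
            hits <- backend(qseq, maxDiff)
            admit <- hits$identity > identityCutoff &
                hits$length_difference < maxDiff &
                !(hits$id %in% c(members, ".seed"))
            admit <- admit & hits$id != q
            for (j in which(admit)) {
                members <- c(members, hits$id[j])
                evidence <- rbind(evidence, data.frame(
                    member = hits$id[j],
                    parent = if (q == ".seed") "<seed>" else q,
                    identity = hits$identity[j],
                    length_difference = hits$length_difference[j],
                    stringsAsFactors = FALSE))
                nextQueue <- c(nextQueue, hits$id[j])
            }
        }
        queue <- setdiff(unique(nextQueue), processed)
    }
    list(members = sort(members), evidence = evidence,
         iterations = iterations)
}
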