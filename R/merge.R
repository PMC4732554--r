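## Terminal-anchor transcript merging.
##
## Two transcripts are merge candidates when a suffix of the upstream
## representative equals a prefix of the downstream one, the shared anchor
## is non-repetitive, the match is one-to-one at that anchor length across
## the whole transcript set, and both identifiers share the same component
## prefix. The default representative is the amino-acid sequence of each
## transcript's longest ORF (the worked geometry of fragmented coding
## regions); a nucleotide mode matches transcript termini directly.

#' Is a string repetitive (low-complexity)?
#'
#' A string built from fewer than three distinct characters is considered
#' repetitive and is never used as a merge anchor, because its uniqueness
#' in the index cannot be trusted.
#'
#' @param s Character vector.
#' @return Logical vector.
#' @examples
#' isRepetitive(c("ABABABAB", "NFDENRGALNSH", "AAAAAAA"))
#' @export
isRepetitive <- function(s) {
    vapply(strsplit(s, "", fixed = TRUE),
           function(ch) length(unique(ch)) < 3L, TRUE)
}

#' Build prefix/suffix terminus indexes
#'
#' For each item and each anchor length \code{n} in \code{lengths}, the
#' length-\code{n} prefix is recorded in the begin index and the
#' length-\code{n} suffix in the end index; repetitive anchors are skipped,
#' and items shorter than \code{n} are indexed only at feasible lengths.
#'
#' @param items Named character vector (id -> sequence).
#' @param lengths Integer range of anchor lengths (default \code{5:15}).
#' @return List with \code{begin} and \code{end}: each a list mapping
#'   anchor string to the character vector of item ids carrying it.
#' @export
buildTerminusIndex <- function(items, lengths = 5:15) {
    begin <- list(); end <- list()
    for (id in names(items)) {
        s <- items[[id]]
        L <- nchar(s)
        for (n in lengths[lengths <= L]) {
            p <- substr(s, 1L, n)
            q <- substr(s, L - n + 1L, L)
            if (!isRepetitive(p)) begin[[p]] <- c(begin[[p]], id)
            if (!isRepetitive(q)) end[[q]] <- c(end[[q]], id)
        }
    }
    list(begin = begin, end = end, lengths = lengths)
}

## Representative sequence per transcript id for a given anchor space.
.mergeReps <- function(transcripts, space, minAa) {
    if (space == "nucleotide")
        return(setNames(as.character(transcriptSeqs(transcripts)),
                        transcriptIds(transcripts)))
    top <- topOrfs(findOrfs(transcripts, minAa = minAa), k = 1L)
    tb <- orfTable(top)
    setNames(tb$aa, tb$transcript_id)
}

## One scan over a fixed representative set: all candidates, maximal anchor
## per ordered pair.
.scanMergePairs <- function(reps, lengths) {
    hitsByPair <- list()
    comp <- setNames(idComponent(names(reps)), names(reps))
    for (n in lengths) {
        ends <- list(); begins <- list()
        for (id in names(reps)) {
            L <- nchar(reps[[id]])
            if (L < n) next
            p <- substr(reps[[id]], 1L, n)
            q <- substr(reps[[id]], L - n + 1L, L)
            if (!isRepetitive(p)) begins[[p]] <- c(begins[[p]], id)
            if (!isRepetitive(q)) ends[[q]] <- c(ends[[q]], id)
        }
        for (anchor in intersect(names(ends), names(begins))) {
            up <- ends[[anchor]]; down <- begins[[anchor]]
            if (length(up) != 1L || length(down) != 1L) next  # one-to-one
            if (up == down) next
            if (comp[[up]] != comp[[down]]) next              # same component
            key <- paste0(up, "\r", down)
            prev <- hitsByPair[[key]]
            if (is.null(prev) || nchar(prev) < n)
                hitsByPair[[key]] <- anchor
        }
    }
    if (length(hitsByPair) == 0L)
        return(data.frame(upstream_id = character(),
                          downstream_id = character(),
                          anchor = character(), anchor_length = integer(),
                          stringsAsFactors = FALSE))
    pairs <- do.call(rbind, strsplit(names(hitsByPair), "\r", fixed = TRUE))
    out <- data.frame(upstream_id = pairs[, 1L],
                      downstream_id = pairs[, 2L],
                      anchor = unlist(hitsByPair, use.names = FALSE),
                      anchor_length = nchar(unlist(hitsByPair,
                                                   use.names = FALSE)),
                      stringsAsFactors = FALSE)
    out[order(out$upstream_id, out$downstream_id), , drop = FALSE]
}

#' Find transcript pairs joinable by a unique terminal anchor
#'
#' Scans representatives for suffix-to-prefix anchor matches of length 5 to
#' 15 (by default), keeps only non-repetitive anchors that map one-to-one
#' across the whole set and pair same-component transcripts, and reports
#' the maximal firing anchor per pair. The scan iterates to a fixed point:
#' each accepted pair is merged and the product (id
#' \code{"<up>+<down>"}) replaces its parents before rescanning, so chains
#' of fragments coalesce and no candidate can pair a product with its own
#' parents.
#'
#' @param transcripts A [TranscriptSet-class].
#' @param space \code{"protein"} (anchors on the longest-ORF amino-acid
#'   sequences; default) or \code{"nucleotide"} (transcript termini).
#' @param lengths Anchor-length range (default \code{5:15}).
#' @param minAa Minimum ORF size used when deriving protein representatives.
#' @return \code{data.frame} of merge candidates: \code{upstream_id},
#'   \code{downstream_id}, \code{anchor}, \code{anchor_length}; the merged
#'   [TranscriptSet-class] after all rounds is attached as attribute
#'   \code{"mergedSet"}.
#' @export
findMergePairs <- function(transcripts, space = c("protein", "nucleotide"),
                           lengths = 5:15, minAa = 10L) {
    space <- match.arg(space)
    work <- transcripts
    all <- list()
    repeat {
        reps <- .mergeReps(work, space, minAa)
        cand <- .scanMergePairs(reps, lengths)
        if (nrow(cand) == 0L) break
        all[[length(all) + 1L]] <- cand
        consumed <- character()
        seqs <- setNames(as.character(transcriptSeqs(work)),
                         transcriptIds(work))
        for (i in seq_len(nrow(cand))) {
            up <- cand$upstream_id[i]; down <- cand$downstream_id[i]
            if (up %in% consumed || down %in% consumed) next
            merged <- applyMerge(work[up], work[down], cand[i, ],
                                 space = space, minAa = minAa)
            seqs <- seqs[setdiff(names(seqs), c(up, down))]
            seqs[transcriptIds(merged)] <- as.character(
                transcriptSeqs(merged))
            consumed <- c(consumed, up, down)
        }
        work <- TranscriptSet(seqs)
    }
    out <- if (length(all)) do.call(rbind, all) else
        data.frame(upstream_id = character(), downstream_id = character(),
                   anchor = character(), anchor_length = integer(),
                   stringsAsFactors = FALSE)
    rownames(out) <- NULL
    attr(out, "mergedSet") <- work
    out
}

#' Merge two transcripts over an anchor
#'
#' Joins the upstream and downstream transcript into one sequence crossing
#' the anchor region once. In nucleotide space the anchor is a direct
#' suffix/prefix of the transcripts. In protein space the anchor lives on
#' the longest-ORF translations and is mapped back through the ORF
#' coordinates; a reverse-strand ORF causes its transcript to be
#' reverse-complemented first so both coding regions read forward. The
#' merged id is \code{"<upstream>+<downstream>"}.
#'
#' @param a,b [TranscriptSet-class] objects of length 1 (upstream,
#'   downstream).
#' @param candidate One-row candidate from [findMergePairs()].
#' @param space \code{"protein"} or \code{"nucleotide"}.
#' @param minAa Minimum ORF size for re-deriving the representatives.
#' @return A [TranscriptSet-class] of length 1 holding the merged
#'   transcript.
#' @export
applyMerge <- function(a, b, candidate, space = c("protein", "nucleotide"),
                       minAa = 10L) {
    space <- match.arg(space)
    stopifnot(length(a) == 1L, length(b) == 1L)
    anchor <- candidate$anchor
    k <- nchar(anchor)
    aId <- transcriptIds(a); bId <- transcriptIds(b)
    stopifnot(aId == candidate$upstream_id, bId == candidate$downstream_id)
    mergedId <- paste0(aId, "+", bId)
    if (space == "nucleotide") {
        aSeq <- as.character(transcriptSeqs(a))[[1L]]
        bSeq <- as.character(transcriptSeqs(b))[[1L]]
        if (substr(aSeq, nchar(aSeq) - k + 1L, nchar(aSeq)) != anchor ||
            substr(bSeq, 1L, k) != anchor)
            stop("stale merge candidate: anchor no longer terminal")
        return(TranscriptSet(setNames(
            paste0(aSeq, substr(bSeq, k + 1L, nchar(bSeq))), mergedId)))
    }
    orient <- function(ts) {
        tb <- orfTable(topOrfs(findOrfs(ts, minAa = minAa), k = 1L))
        if (nrow(tb) == 0L) stop("stale merge candidate: no ORF left")
        seq <- as.character(transcriptSeqs(ts))[[1L]]
        if (tb$strand == "reverse") {
            seq <- as.character(reverseComplement(DNAString(seq)))
            L <- nchar(seq)
            tb[, c("nt_start", "nt_end")] <-
                c(L - tb$nt_end + 1L, L - tb$nt_start + 1L)
        }
        list(seq = seq, aa = tb$aa, s = tb$nt_start, e = tb$nt_end)
    }
    ao <- orient(a); bo <- orient(b)
    if (substr(ao$aa, nchar(ao$aa) - k + 1L, nchar(ao$aa)) != anchor ||
        substr(bo$aa, 1L, k) != anchor)
        stop("stale merge candidate: anchor not on ORF termini")
    ## keep upstream through the end of its ORF (anchor inclusive), then
    ## append downstream from just past its anchor codons
    upPart <- substr(ao$seq, 1L, ao$e)
    downPart <- substr(bo$seq, bo$s + 3L * k, nchar(bo$seq))
    TranscriptSet(setNames(paste0(upPart, downPart), mergedId))
}
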