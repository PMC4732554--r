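## Evidence-based partition of transcripts.
##
## Precedence: LONG_REPEAT > BROKEN_ORF_ERROR > (score-dominant unique) >
## MULTI_GENE > UNIQUE_HIGH > UNIQUE_LOW > NO_HIT. A transcript whose top
## ORFs carry >=2 best hits to one subject accession (each below the
## broken-ORF band) is an assembly/sequencing error; identical duplicated
## ORFs mark a long-repeat misassembly and take precedence over everything
## hit-based, since identical ORFs would trivially satisfy the broken-ORF
## rule.

#' Classification thresholds
#'
#' @param highEvalue E-value below which a match counts as high
#'   significance (partition band; default \code{1e-12}).
#' @param lowerEvalue Upper bound of the lower-significance band (default
#'   \code{1e-8}); best E-values in \code{[highEvalue, lowerEvalue)} give
#'   \code{UNIQUE_LOW}.
#' @param errorEvalue Band for the broken-ORF test (default \code{1e-10});
#'   kept as a separate knob from \code{highEvalue} because the two bands
#'   serve different decisions.
#' @param scoreRatio An ORF is uniquely annotated when its bit score exceeds
#'   \code{scoreRatio} times every other ORF's best bit score, even if the
#'   others pass the E-value band (default 2).
#' @param stopwords Title keywords suppressed when selecting a functional
#'   annotation (case-insensitive substrings).
#' @return A validated list of class \code{curation_thresholds}.
#' @export
curationThresholds <- function(highEvalue = 1e-12, lowerEvalue = 1e-8,
                               errorEvalue = 1e-10, scoreRatio = 2,
                               stopwords = c("chromosome", "hypothetical",
                                             "unnamed", "unknown",
                                             "uncharacterized")) {
    stopifnot(highEvalue <= lowerEvalue, scoreRatio > 1,
              highEvalue > 0, lowerEvalue > 0, errorEvalue > 0)
    structure(list(highEvalue = highEvalue, lowerEvalue = lowerEvalue,
                   errorEvalue = errorEvalue, scoreRatio = scoreRatio,
                   stopwords = tolower(stopwords)),
              class = "curation_thresholds")
}

#' Best hit per ORF
#'
#' Per query ORF, the hit with the smallest E-value; ties broken by larger
#' bit score, then lexicographically smallest subject accession, so the
#' choice is independent of row order.
#'
#' @param hits Hit \code{data.frame} (see [readHits()]).
#' @return Hit \code{data.frame} with one row per \code{qseqid}.
#' @export
bestHitPerOrf <- function(hits) {
    if (nrow(hits) == 0L) return(hits)
    o <- order(hits$qseqid, hits$evalue, -hits$bitscore, hits$sseqid)
    h <- hits[o, , drop = FALSE]
    h[!duplicated(h$qseqid), , drop = FALSE]
}

#' Detect identical duplicated ORFs (long repeats)
#'
#' @param orfs [OrfSet-class] or ORF \code{data.frame} for one transcript.
#' @return \code{NULL}, or a list with \code{aa} (the repeated protein) and
#'   \code{orf_ids} of the group of >= 2 ORFs sharing an identical
#'   translation (any strands).
#' @export
detectLongRepeat <- function(orfs) {
    tb <- if (is(orfs, "OrfSet")) orfTable(orfs) else orfs
    if (nrow(tb) < 2L) return(NULL)
    stopifnot(length(unique(tb$transcript_id)) == 1L)
    dup <- tb$aa[duplicated(tb$aa)]
    if (length(dup) == 0L) return(NULL)
    ## largest repeated group; ties resolved by longer ORF then first seen
    groups <- split(tb$orf_id, tb$aa)
    groups <- groups[lengths(groups) >= 2L]
    sz <- lengths(groups)
    ln <- nchar(names(groups))
    pick <- order(-sz, -ln, names(groups))[1L]
    list(aa = names(groups)[pick], orf_ids = unname(groups[[pick]]))
}

## Subject-coordinate interval of a hit, normalized so start <= end.
.subjInterval <- function(h) {
    cbind(pmin(h$sstart, h$send), pmax(h$sstart, h$send))
}

#' Detect a broken ORF (same-gene multi-ORF error)
#'
#' If at least two distinct ORFs' best hits share one subject accession,
#' each with E-value below \code{errorEvalue}, the transcript carries a
#' putative sequencing/assembly error. The breakpoint hint is the gap (or
#' abutment point) between the two hits' subject-coordinate intervals,
#' localizing the lesion on the matched protein.
#'
#' @param bestHits Per-ORF best hits of one transcript ([bestHitPerOrf()]).
#' @param errorEvalue E-value band for the test (default \code{1e-10}).
#' @return \code{NULL}, or a list with \code{subject_accession},
#'   \code{orf_ids}, and \code{breakpoint} (\code{c(start, end)} in subject
#'   coordinates, or \code{NULL} when the intervals overlap).
#' @export
detectBrokenOrf <- function(bestHits, errorEvalue = 1e-10) {
    h <- bestHits[bestHits$evalue < errorEvalue, , drop = FALSE]
    if (nrow(h) < 2L) return(NULL)
    tab <- table(h$sseqid)
    shared <- names(tab)[tab >= 2L]
    if (length(shared) == 0L) return(NULL)
    ## choose the shared accession with the most significant evidence
    bestEv <- vapply(shared, function(s) min(h$evalue[h$sseqid == s]), 0)
    acc <- shared[order(bestEv, shared)][1L]
    hh <- h[h$sseqid == acc, , drop = FALSE]
    hh <- hh[order(hh$evalue, -hh$bitscore), , drop = FALSE][1:2, ]
    iv <- .subjInterval(hh)
    iv <- iv[order(iv[, 1L]), , drop = FALSE]
    bp <- if (iv[2L, 1L] > iv[1L, 2L]) c(iv[1L, 2L], iv[2L, 1L]) else NULL
    list(subject_accession = acc,
         orf_ids = h$qseqid[h$sseqid == acc],
         breakpoint = bp)
}

#' Detect a transcript carrying two valid genes
#'
#' If two or more ORFs have best hits to distinct subject accessions, each
#' below the high-significance band, the transcript encodes multiple genes;
#' one annotation record is emitted per ORF (the transcript is effectively
#' duplicated, one copy per protein). The transcript is additionally a
#' chimera/fusion candidate when the qualifying ORFs lie on one strand and
#' do not overlap on the transcript.
#'
#' @param bestHits Per-ORF best hits of one transcript.
#' @param highEvalue High-significance band (default \code{1e-12}).
#' @param orfs ORF \code{data.frame} of the same transcript (for strand and
#'   coordinates).
#' @return \code{NULL}, or a list with \code{records} (annotation
#'   \code{data.frame}) and \code{chimera} (logical).
#' @export
detectMultiGene <- function(bestHits, highEvalue = 1e-12, orfs) {
    tb <- if (is(orfs, "OrfSet")) orfTable(orfs) else orfs
    h <- bestHits[bestHits$evalue < highEvalue, , drop = FALSE]
    if (nrow(h) < 2L || length(unique(h$sseqid)) < 2L) return(NULL)
    m <- match(h$qseqid, tb$orf_id)
    rec <- data.frame(transcript_id = tb$transcript_id[m],
                      orf_id = h$qseqid,
                      subject_accession = h$sseqid,
                      subject_title = h$stitle,
                      evalue = h$evalue, bitscore = h$bitscore,
                      strand = tb$strand[m], stringsAsFactors = FALSE)
    sameStrand <- length(unique(tb$strand[m])) == 1L
    ## pairwise disjoint on the forward transcript axis
    s <- tb$nt_start[m]; e <- tb$nt_end[m]
    o <- order(s)
    disjoint <- all(s[o][-1L] > e[o][-length(o)])
    list(records = rec[order(rec$evalue, rec$orf_id), , drop = FALSE],
         chimera = sameStrand && disjoint)
}

#' Select the single functional annotation of a uniquely annotated ORF
#'
#' Among the qualifying hits (already restricted to the E-value band), the
#' lowest-E-value hit whose title contains no stopword is preferred, to keep
#' a functional characteristic in the annotation; when every title is
#' stopworded (or titles are absent) the overall best hit is kept anyway,
#' provided it passed the band.
#'
#' @param hits Qualifying hits of the chosen ORF.
#' @param stopwords Lower-cased keywords to avoid (substring match).
#' @return One-row hit \code{data.frame} (the selected annotation).
#' @export
selectUniqueAnnotation <- function(hits,
                                   stopwords = curationThresholds()$stopwords) {
    if (nrow(hits) == 0L)
        stop("selectUniqueAnnotation requires at least one qualifying hit")
    o <- order(hits$evalue, -hits$bitscore, hits$sseqid)
    h <- hits[o, , drop = FALSE]
    titles <- tolower(ifelse(is.na(h$stitle), "", h$stitle))
    clean <- !vapply(titles, function(tt)
        any(vapply(stopwords, grepl, TRUE, x = tt, fixed = TRUE)), TRUE)
    h[if (any(clean)) which(clean)[1L] else 1L, , drop = FALSE]
}

## Classify one transcript given its top ORFs and their hits.
.classifyOne <- function(tid, tb, hits, th) {
    empty <- data.frame(transcript_id = character(), orf_id = character(),
                        subject_accession = character(),
                        subject_title = character(), evalue = numeric(),
                        bitscore = numeric(), strand = character(),
                        stringsAsFactors = FALSE)
    cls <- function(class, chim = FALSE, bp = NULL, bpSubj = NA_character_,
                    ann = empty)
        list(row = data.frame(transcript_id = tid, class = class,
                              chimera_candidate = chim,
                              breakpoint_subject = bpSubj,
                              breakpoint_start = if (is.null(bp)) NA_real_
                                                 else bp[1L],
                              breakpoint_end = if (is.null(bp)) NA_real_
                                               else bp[2L],
                              stringsAsFactors = FALSE),
             ann = ann)
    recFromHits <- function(h) {
        m <- match(h$qseqid, tb$orf_id)
        data.frame(transcript_id = tid, orf_id = h$qseqid,
                   subject_accession = h$sseqid, subject_title = h$stitle,
                   evalue = h$evalue, bitscore = h$bitscore,
                   strand = tb$strand[m], stringsAsFactors = FALSE)
    }

    rep <- detectLongRepeat(tb)
    best <- bestHitPerOrf(hits)
    if (!is.null(rep)) {
        ann <- recFromHits(best[best$qseqid %in% rep$orf_ids, , drop = FALSE])
        return(cls("LONG_REPEAT", ann = ann))
    }
    if (nrow(best)) {
        br <- detectBrokenOrf(best, th$errorEvalue)
        if (!is.null(br)) {
            ann <- recFromHits(best[best$qseqid %in% br$orf_ids, ,
                                    drop = FALSE])
            return(cls("BROKEN_ORF_ERROR", bp = br$breakpoint,
                       bpSubj = br$subject_accession, ann = ann))
        }
        highOrfs <- best[best$evalue < th$highEvalue, , drop = FALSE]
        if (nrow(highOrfs) >= 2L) {
            ## twice-the-score dominance: one ORF can be unique even when
            ## others pass the band
            o <- order(-highOrfs$bitscore)
            dom <- highOrfs$bitscore[o][1L] >
                th$scoreRatio * highOrfs$bitscore[o][2L]
            if (!dom) {
                mg <- detectMultiGene(best, th$highEvalue, tb)
                if (!is.null(mg))
                    return(cls("MULTI_GENE", chim = mg$chimera,
                               ann = mg$records))
            }
            winner <- highOrfs$qseqid[o][1L]
            band <- hits[hits$qseqid == winner &
                         hits$evalue < th$highEvalue, , drop = FALSE]
            return(cls("UNIQUE_HIGH",
                       ann = recFromHits(selectUniqueAnnotation(
                           band, th$stopwords))))
        }
        if (nrow(highOrfs) == 1L) {
            band <- hits[hits$qseqid == highOrfs$qseqid &
                         hits$evalue < th$highEvalue, , drop = FALSE]
            return(cls("UNIQUE_HIGH",
                       ann = recFromHits(selectUniqueAnnotation(
                           band, th$stopwords))))
        }
        lowBest <- best[best$evalue < th$lowerEvalue, , drop = FALSE]
        if (nrow(lowBest)) {
            win <- lowBest$qseqid[order(lowBest$evalue,
                                        -lowBest$bitscore)][1L]
            band <- hits[hits$qseqid == win &
                         hits$evalue < th$lowerEvalue, , drop = FALSE]
            return(cls("UNIQUE_LOW",
                       ann = recFromHits(selectUniqueAnnotation(
                           band, th$stopwords))))
        }
    }
    cls("NO_HIT")
}

#' Partition a transcriptome by ORF homology evidence
#'
#' Applies the full precedence chain per transcript: identical duplicated
#' ORFs (LONG_REPEAT), multiple ORFs hitting one subject entry
#' (BROKEN_ORF_ERROR, with a subject-coordinate breakpoint hint), a
#' score-dominant or single high-significance ORF (UNIQUE_HIGH), multiple
#' high-significance ORFs on distinct entries (MULTI_GENE, chimera-flagged
#' when same-strand and non-overlapping), a lower-band best match
#' (UNIQUE_LOW), else NO_HIT. Every transcript receives exactly one class.
#'
#' @param transcripts A [TranscriptSet-class].
#' @param hits Hit \code{data.frame} over the transcripts' ORFs.
#' @param orfs Optional precomputed [OrfSet-class]; found with default
#'   settings when \code{NULL}.
#' @param thresholds A [curationThresholds()] list.
#' @param k Number of longest ORFs considered per transcript (default 3).
#' @return A [ClassificationResult-class].
#' @export
classifyTranscripts <- function(transcripts, hits, orfs = NULL,
                                thresholds = curationThresholds(),
                                k = 3L) {
    if (is.null(orfs)) orfs <- findOrfs(transcripts)
    top <- topOrfs(orfs, k)
    tb <- orfTable(top)
    hits <- hits[hits$qseqid %in% tb$orf_id, , drop = FALSE]
    ids <- transcriptIds(transcripts)
    out <- lapply(ids, function(tid) {
        ttb <- tb[tb$transcript_id == tid, , drop = FALSE]
        if (nrow(ttb) == 0L)
            return(.classifyOne(tid, ttb, hits[0, , drop = FALSE],
                                thresholds))
        .classifyOne(tid, ttb,
                     hits[hits$qseqid %in% ttb$orf_id, , drop = FALSE],
                     thresholds)
    })
    emptyClasses <- data.frame(transcript_id = character(),
                               class = character(),
                               chimera_candidate = logical(),
                               breakpoint_subject = character(),
                               breakpoint_start = numeric(),
                               breakpoint_end = numeric(),
                               stringsAsFactors = FALSE)
    emptyAnn <- data.frame(transcript_id = character(), orf_id = character(),
                           subject_accession = character(),
                           subject_title = character(), evalue = numeric(),
                           bitscore = numeric(), strand = character(),
                           stringsAsFactors = FALSE)
    classes <- if (length(out)) do.call(rbind, lapply(out, `[[`, "row"))
               else emptyClasses
    anns <- if (length(out)) do.call(rbind, lapply(out, `[[`, "ann"))
            else emptyAnn
    rownames(classes) <- rownames(anns) <- NULL
    new("ClassificationResult", classes = classes, annotations = anns)
}
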