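## Count normalization, abundance ranking, and amino-acid composition
## profiling of representative ORFs.

#' Length-normalize raw transcript counts
#'
#' Applies \code{normalized = 100 * raw / length(transcript)} (the constant
#' reflecting a nominal 100-nt read length); transcripts with zero raw
#' counts are dropped from the result, since they carry no abundance
#' signal for ranking.
#'
#' @param counts \code{data.frame} with \code{transcript_id} and \code{raw}
#'   (see [readCounts()]).
#' @param transcripts A [TranscriptSet-class] providing transcript lengths.
#' @return \code{data.frame} with \code{transcript_id}, \code{raw},
#'   \code{length_nt}, \code{normalized}.
#' @examples
#' ts <- TranscriptSet(c(t1 = paste(rep("ACGT", 25), collapse = "")))
#' normalizeCounts(data.frame(transcript_id = "t1", raw = 73), ts)
#' @export
normalizeCounts <- function(counts, transcripts) {
    lens <- setNames(width(transcriptSeqs(transcripts)),
                     transcriptIds(transcripts))
    orphans <- setdiff(counts$transcript_id, names(lens))
    if (length(orphans))
        stop("count records without a transcript: ",
             paste(orphans, collapse = ", "))
    keep <- counts$raw > 0
    df <- counts[keep, , drop = FALSE]
    df$length_nt <- as.integer(lens[df$transcript_id])
    df$normalized <- 100 * df$raw / df$length_nt
    rownames(df) <- NULL
    df[, c("transcript_id", "raw", "length_nt", "normalized")]
}

#' Rank transcripts by normalized abundance
#'
#' @param normCounts Output of [normalizeCounts()].
#' @param k Number of top transcripts to return (default: all).
#' @return The input rows ordered by descending \code{normalized}; ties
#'   broken by transcript id, so the ranking is a stable total order.
#' @export
rankTranscripts <- function(normCounts, k = Inf) {
    o <- order(-normCounts$normalized, normCounts$transcript_id)
    out <- normCounts[o, , drop = FALSE]
    rownames(out) <- NULL
    head(out, n = if (is.finite(k)) k else nrow(out))
}

#' Amino-acid composition of a protein
#'
#' @param aa Protein string (e.g. one ORF translation), an \code{AAString},
#'   or a single-row [OrfSet-class].
#' @return List of class \code{aa_composition}: \code{percent} (named,
#'   unrounded, sums to 100), \code{rounded} (nearest integer percent, the
#'   reporting form), \code{top_residues} (residues by descending
#'   percentage), and \code{n} (residue count).
#' @export
aaComposition <- function(aa) {
    if (is(aa, "OrfSet")) {
        stopifnot(length(aa) == 1L)
        aa <- orfTable(aa)$aa
    }
    aa <- as.character(aa)
    stopifnot(nzchar(aa))
    cnt <- table(strsplit(aa, "", fixed = TRUE)[[1L]])
    pct <- 100 * as.numeric(cnt) / nchar(aa)
    names(pct) <- names(cnt)
    pct <- sort(pct, decreasing = TRUE)
    structure(list(percent = pct, rounded = round(pct),
                   top_residues = names(pct), n = nchar(aa)),
              class = "aa_composition")
}

#' @export
print.aa_composition <- function(x, ...) {
    cat("Amino-acid composition over", x$n, "residues\n")
    print(x$rounded)
    invisible(x)
}

#' Default composition classification rules
#'
#' Heuristic, composition-derived labels. Thresholds are reverse-engineered
#' from two exemplar wall proteins (a proline-rich protein at 19\% proline;
#' a leucine/histidine/valine-rich putative extensin at 18/13/10\%) and are
#' fully configurable; they are flags for follow-up, not assignments.
#'
#' @return List of rules; each rule has \code{label}, optional \code{min}
#'   (named per-residue minimum percents) and optional \code{groupMin}
#'   (list with \code{residues} and \code{total} percent).
#' @export
compositionRules <- function() {
    list(list(label = "proline-rich", min = c(P = 15)),
         list(label = "putative extensin (L/H/V-rich)",
              min = c(L = 8, H = 8, V = 8),
              groupMin = list(residues = c("L", "H", "V"), total = 35)))
}

#' Flag a composition class
#'
#' Applies the ordered rule set to an unrounded composition profile; the
#' first rule whose per-residue minima (and group total, if any) are met
#' fires. The result is marked heuristic.
#'
#' @param profile An \code{aa_composition} from [aaComposition()].
#' @param rules Rule set (default [compositionRules()]).
#' @return The firing rule's label (character, attribute
#'   \code{heuristic = TRUE}), or \code{NA_character_} when no rule fires.
#' @export
flagCompositionClass <- function(profile, rules = compositionRules()) {
    pct <- profile$percent
    at <- function(r) if (r %in% names(pct)) pct[[r]] else 0
    for (rule in rules) {
        ok <- TRUE
        if (!is.null(rule$min))
            ok <- all(vapply(names(rule$min),
                             function(r) at(r) >= rule$min[[r]], TRUE))
        if (ok && !is.null(rule$groupMin))
            ok <- sum(vapply(rule$groupMin$residues, at, 0)) >=
                rule$groupMin$total
        if (ok) return(structure(rule$label, heuristic = TRUE))
    }
    NA_character_
}
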