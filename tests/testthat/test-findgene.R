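test_that("pairwise identity matches direct counting and the DP oracle", {
    expect_equal(unname(pairwiseIdentity("MKLV", "MKLV")["identity"]), 100)
    expect_equal(unname(pairwiseIdentity("MKLV", "MKLV")["length_difference"]), 0)
    expect_equal(unname(pairwiseIdentity("AAAA", "AAAT")["identity"]), 75)
    ## related pairs (substitutions, then an indel) have an essentially
    ## unique optimal alignment; the aligner must agree with the DP oracle
    set.seed(55)
    aaAlphabet <- setdiff(LETTERS, c("B", "J", "O", "U", "X", "Z"))
    for (i in 1:8) {
        n <- sample(40:60, 1L)
        a <- rprot(n)
        ch <- strsplit(a, "")[[1L]]
        at <- sample(n, sample(5:15, 1L))
        for (p in at) ch[p] <- sample(setdiff(aaAlphabet, ch[p]), 1L)
        b <- paste(ch, collapse = "")
        got <- unname(pairwiseIdentity(a, b)["identity"])
        expect_lt(abs(got - nwIdentity(a, b)), 1.0001)
        expect_equal(got, 100 * (n - length(at)) / n, tolerance = 0.02)
        ## single internal insertion
        cut <- sample(10:(n - 10), 1L)
        b2 <- paste0(substr(a, 1, cut), "WWW", substr(a, cut + 1, n))
        got2 <- unname(pairwiseIdentity(a, b2)["identity"])
        expect_lt(abs(got2 - nwIdentity(a, b2)), 1.0001)
        expect_equal(unname(pairwiseIdentity(a, b2)["length_difference"]), 3)
    }
})

test_that("a seed with no admissible hit yields an empty family", {
    db <- setNames(c(rprot(80), rprot(200)), c("x", "y"))
    set.seed(60)
    fam <- findGeneFamily(rprot(140), db)
    expect_length(fam$members, 0L)
    expect_equal(fam$iterations, 1L)
})

test_that("chained homology requires iteration to recover the far member", {
    ch <- chainFamily()
    db <- c(B = ch$B, C = ch$C)
    fam <- findGeneFamily(ch$A, db, identityCutoff = 40, lengthCutoff = 50)
    expect_setequal(fam$members, c("B", "C"))
    expect_gte(fam$iterations, 2L)
    # C is not reachable from the seed directly
    direct <- pairwiseIdentity(ch$A, ch$C)["identity"]
    expect_lt(direct, 40)
    # every evidence edge replays above both cutoffs
    for (i in seq_len(nrow(fam$evidence))) {
        e <- fam$evidence[i, ]
        parent <- if (e$parent == "<seed>") ch$A else db[[e$parent]]
        pi <- pairwiseIdentity(parent, db[[e$member]])
        expect_gt(pi["identity"], 40)
        expect_lt(pi["length_difference"], 50)
    }
})

test_that("the member set is invariant to database ordering", {
    ch <- chainFamily()
    set.seed(61)
    db <- c(B = ch$B, C = ch$C,
            setNames(vapply(1:5, function(i) rprot(100), ""),
                     paste0("d", 1:5)))
    f1 <- findGeneFamily(ch$A, db)
    f2 <- findGeneFamily(ch$A, rev(db))
    expect_identical(f1$members, f2$members)
})

test_that("lowering the identity cutoff never shrinks the family", {
    ch <- chainFamily()
    set.seed(62)
    db <- c(B = ch$B, C = ch$C,
            setNames(vapply(1:4, function(i) rprot(100), ""),
                     paste0("d", 1:4)))
    prev <- character()
    for (cut in c(60, 44, 30, 10)) {
        fam <- findGeneFamily(ch$A, db, identityCutoff = cut)
        expect_true(all(prev %in% fam$members))
        prev <- fam$members
        expect_lte(length(fam$members), length(db))
    }
})

test_that("percent length mode scales the cutoff to the query", {
    set.seed(63)
    base <- rprot(100)
    db <- c(long = paste0(base, rprot(40)))   # 140 residues, shares 100
    # absolute mode: |100 - 140| = 40 < 50 admits
    expect_equal(findGeneFamily(base, db, identityCutoff = 30,
                                lengthCutoff = 50)$members, "long")
    # percent mode: 40 residues is 40% of the query, above a 30% cutoff
    expect_length(findGeneFamily(base, db, identityCutoff = 30,
                                 lengthCutoff = 30,
                                 lengthMode = "percent")$members, 0L)
})
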