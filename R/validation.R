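#' @include utils.R
NULL

# ---------------------------------------------------------------- Fisher test

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact enumeration under the hypergeometric null with both margins
#' fixed: the two-sided P value is the sum of the point probabilities of
#' all tables (with the same margins) whose probability does not exceed
#' that of the observed table, using a relative tolerance of 1e-7 on the
#' comparison. No normal approximation is involved.
#'
#' @param t a 2x2 matrix (or 4-vector a, b, c, d filled by row) of
#'   non-negative counts.
#' @return the two-sided P value.
#' @examples
#' fisherExactTwoSided(matrix(c(7, 0, 0, 13), 2, byrow = TRUE))
#' @export
fisherExactTwoSided <- function(t) {
    t <- as.vector(t(matrix(as.numeric(t), 2, 2)))
    if (any(is.na(t)) || any(t < 0))
        .stopf("the 2x2 table must contain non-negative counts")
    a <- t[1]; b <- t[2]; c_ <- t[3]; d <- t[4]
    r1 <- a + b; r2 <- c_ + d; c1 <- a + c_
    lo <- max(0, c1 - r2); hi <- min(r1, c1)
    x <- lo:hi
    p <- dhyper(x, r1, r2, c1)
    p0 <- dhyper(a, r1, r2, c1)
    sum(p[p <= p0 * (1 + 1e-7)])
}

# ------------------------------------------------------------------ Spearman

#' Spearman rank correlation with mid-rank ties
#'
#' rho is the Pearson correlation of the mid-ranked vectors; significance
#' uses the t-approximation with n - 2 degrees of freedom at a two-sided
#' alpha of 0.05 (the NS / significant dichotomy reported alongside
#' markers).
#'
#' @param x,y equal-length numeric/ordinal vectors, length >= 3.
#' @return list with elements `rho`, `p_value`, `significant`.
#' @examples
#' spearmanRho(c(1, 2, 3), c(3, 2, 1))
#' @export
spearmanRho <- function(x, y) {
    x <- as.numeric(x); y <- as.numeric(y)
    if (length(x) != length(y)) .stopf("x and y must have equal length")
    if (length(x) < 3) .stopf("need at least 3 observations")
    if (length(unique(x)) < 2 || length(unique(y)) < 2)
        .stopf("rho undefined: zero variance in x or y")
    ct <- suppressWarnings(cor.test(x, y, method = "spearman",
        exact = FALSE, alternative = "two.sided"))
    list(rho = unname(ct$estimate), p_value = ct$p.value,
         significant = ct$p.value < 0.05)
}

# ------------------------------------------------------------- phenotypes IO

# ordinal encoding of the spoilage-potential classes; exposed as an
# argument because published tables print only the class labels
.default_rank_levels <- c(NB = 0, WB = 1, MB = 2, SB = 3)

#' Read a strain phenotype table
#'
#' TSV with columns `strain`, optionally `ability`
#' (`spoiler`/`non_spoiler`) and `potential_rank` (class label or numeric
#' rank). When `ability` is absent it is derived from the rank: a strain
#' is a spoiler when its rank is at least that of class MB (growth in the
#' mid-bitterness test beer).
#'
#' @param path TSV path.
#' @param rank_levels named numeric encoding of the ordinal classes
#'   (default NB=0 < WB=1 < MB=2 < SB=3).
#' @return data.frame with columns `strain`, `ability`, `potential_rank`.
#' @export
readPhenotypes <- function(path, rank_levels = .default_rank_levels) {
    df <- read.delim(path, stringsAsFactors = FALSE)
    if (!"strain" %in% names(df)) .stopf("phenotype table needs a 'strain' column")
    if (!"potential_rank" %in% names(df))
        .stopf("phenotype table needs a 'potential_rank' column")
    pr <- df$potential_rank
    if (is.character(pr)) {
        unknown <- setdiff(unique(pr), names(rank_levels))
        if (length(unknown))
            .stopf("unknown spoilage class label(s): %s",
                paste(unknown, collapse = ", "))
        pr <- unname(rank_levels[pr])
    }
    ability <- if ("ability" %in% names(df)) df$ability else
        ifelse(pr >= rank_levels["MB"], "spoiler", "non_spoiler")
    bad <- !ability %in% c("spoiler", "non_spoiler")
    if (any(bad)) .stopf("ability must be 'spoiler' or 'non_spoiler'")
    data.frame(strain = as.character(df$strain), ability = ability,
        potential_rank = as.numeric(pr), stringsAsFactors = FALSE)
}

#' Read a marker presence matrix
#'
#' TSV with markers as rows (first column the marker name) and strains as
#' columns; cells 0/1.
#'
#' @param path TSV path.
#' @return integer matrix markers x strains.
#' @export
readPresenceMatrix <- function(path) {
    df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
    storage.mode(m) <- "integer"
    if (any(is.na(m)) || !all(m %in% c(0L, 1L)))
        .stopf("presence matrix cells must be 0/1 with no missing values")
    m
}

# ---------------------------------------------------------- confusion counts

#' Confusion counts of one marker against the spoilage phenotype
#'
#' With spoilers as the positive class: `a` = marker-positive spoilers,
#' `b` = marker-negative spoilers (false negatives), `c` = marker-positive
#' non-spoilers (false positives), `d` = marker-negative non-spoilers.
#'
#' @param presence named 0/1 (or logical) vector of marker presence per
#'   strain.
#' @param pheno phenotype data.frame as from [readPhenotypes()].
#' @return list with elements `a`, `b`, `c`, `d`, `n_spoilers`,
#'   `n_non_spoilers`, `correct_pct`, and `table` (the 2x2 matrix).
#' @export
confusionCounts <- function(presence, pheno) {
    if (is.null(names(presence)))
        .stopf("presence vector must be named by strain")
    missing_ <- setdiff(names(presence), pheno$strain)
    if (length(missing_))
        .stopf("strain(s) missing from phenotype table: %s",
            paste(missing_, collapse = ", "))
    ab <- pheno$ability[match(names(presence), pheno$strain)]
    pos <- as.logical(presence)
    sp <- ab == "spoiler"
    a <- sum(sp & pos); b <- sum(sp & !pos)
    c_ <- sum(!sp & pos); d <- sum(!sp & !pos)
    n <- a + b + c_ + d
    list(a = a, b = b, c = c_, d = d,
         n_spoilers = a + b, n_non_spoilers = c_ + d,
         correct_pct = 100 * (a + d) / n,
         table = matrix(c(a, b, c_, d), 2, 2, byrow = TRUE,
             dimnames = list(c("spoiler", "non_spoiler"),
                             c("positive", "negative"))))
}

#' Evaluate all markers of a presence matrix against phenotypes
#'
#' Per marker: confusion counts and correct discrimination against the
#' binary spoilage ability, the two-sided Fisher exact P, and the Spearman
#' rank correlation of presence with the ordinal spoilage potential (the
#' rho of markers not significant at CI 95 is rendered `NS`). Markers are
#' sorted by descending Fisher P (worst discriminators first).
#'
#' @param matrix integer markers x strains presence matrix
#'   (see [readPresenceMatrix()]).
#' @param pheno phenotype data.frame as from [readPhenotypes()].
#' @return data.frame with columns `marker`, `fisher_p`, `spearman_rho`,
#'   `rho_display`, `correct_pct`, `false_positive`, `false_negative`,
#'   `n_spoilers`, `n_non_spoilers`.
#' @export
evaluateMarkers <- function(matrix, pheno) {
    if (nrow(matrix) < 1) .stopf("need at least one marker")
    rows <- lapply(rownames(matrix), function(mk) {
        cc <- confusionCounts(matrix[mk, ], pheno)
        fp <- fisherExactTwoSided(cc$table)
        rank_ <- pheno$potential_rank[match(colnames(matrix), pheno$strain)]
        sr <- tryCatch(spearmanRho(matrix[mk, ], rank_),
            error = function(e) list(rho = NA_real_, p_value = NA_real_,
                significant = FALSE))
        data.frame(marker = mk, fisher_p = fp,
            spearman_rho = sr$rho,
            rho_display = if (isTRUE(sr$significant))
                sprintf("%.2f", sr$rho) else "NS",
            correct_pct = cc$correct_pct,
            false_positive = cc$c, false_negative = cc$b,
            n_spoilers = cc$n_spoilers, n_non_spoilers = cc$n_non_spoilers,
            stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out <- out[order(-out$fisher_p, out$marker), , drop = FALSE]
    rownames(out) <- NULL
    out
}
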