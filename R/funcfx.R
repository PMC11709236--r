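#' Filter canonical pathways by direction and significance
#'
#' Directional pathways (non-missing, non-zero z-score) are dropped when
#' their -log10(p) falls below the threshold (default 1.3, i.e. p = 0.05);
#' the survivors are labelled \code{enhanced} (z > 0) or \code{repressed}
#' (z < 0). Neutral pathways (z missing or 0) are retained, as major
#' bidirectional gene sets, only when -log10(p) exceeds the threshold.
#'
#' @param records data.frame with columns \code{pathway}, \code{z},
#'   \code{p} (and optionally \code{comparison}).
#' @param threshold -log10(p) cut-off, default 1.3.
#' @return the records with added \code{negLog10P} and \code{status} in
#'   \{\code{enhanced}, \code{repressed}, \code{neutral},
#'   \code{filtered-out}\}.
#' @export
filterPathways <- function(records, threshold = 1.3) {
    if (any(is.na(records$p)) || any(records$p <= 0) || any(records$p > 1))
        stop("p-values must lie in (0, 1]")
    nl <- -log10(records$p)
    neutral <- is.na(records$z) | records$z == 0
    status <- character(nrow(records))
    status[!neutral & nl < threshold] <- "filtered-out"
    status[!neutral & nl >= threshold & records$z > 0] <- "enhanced"
    status[!neutral & nl >= threshold & records$z < 0] <- "repressed"
    status[neutral] <- ifelse(nl[neutral] > threshold, "neutral",
                              "filtered-out")
    records$negLog10P <- nl
    records$status <- status
    records
}

denseRank <- function(x) match(x, sort(unique(x), decreasing = TRUE))

#' Classify upstream regulators against observed expression
#'
#' Regulators without a significant expression record are dropped. A
#' regulator is \code{major} when its predicted activation z-score exceeds
#' +/- \code{zMajor} (default 2.0), and a \code{match} when a
#' predicted-activated regulator (z >= zMajor) is observed up in H
#' (log2FC > 0, H-vs-L convention) or a predicted-inhibited one
#' (z <= -zMajor) is observed up in L (log2FC < 0). Among matching genes of
#' each group, dense ranks by |z| and by |log2FC| drive the top-k lists.
#'
#' @param regs data.frame with columns \code{ortholog} and \code{z}.
#' @param deg data.frame with columns \code{ortholog}, \code{log2FC} and
#'   optionally \code{significant} (default all TRUE); the H-vs-L
#'   consolidated expression table.
#' @param zMajor major-regulator threshold on |z| (default 2).
#' @param topK size of the per-group top lists (default 10).
#' @return list with \code{records} (flags and ranks per regulator),
#'   \code{topByZ} and \code{topByExpression} (per-group lists), and
#'   \code{summary} counts.
#' @export
classifyRegulators <- function(regs, deg, zMajor = 2, topK = 10) {
    if (NROW(regs) == 0L) stop("regulator table is empty")
    if (is(deg, "ConsolidatedTable")) {
        deg <- data.frame(ortholog = deg$ortholog,
                          log2FC = (deg$selLFC1 + deg$selLFC2) / 2,
                          significant = TRUE)
    }
    if (is.null(deg$significant)) deg$significant <- TRUE
    deg <- deg[deg$significant, , drop = FALSE]
    idx <- match(regs$ortholog, deg$ortholog)
    dropped <- sum(is.na(idx))
    if (dropped > 0)
        message(dropped, " regulator(s) without significant expression dropped")
    keep <- !is.na(idx)
    rec <- data.frame(ortholog = regs$ortholog[keep], z = regs$z[keep],
                      log2FC = deg$log2FC[idx[keep]])
    rec <- rec[order(rec$ortholog), , drop = FALSE]
    rec$predictedState <- ifelse(rec$z > 0, "activated", "inhibited")
    rec$group <- ifelse(rec$log2FC > 0, "H", "L")
    rec$isMajor <- abs(rec$z) >= zMajor
    rec$isMatch <- (rec$z >= zMajor & rec$log2FC > 0) |
                   (rec$z <= -zMajor & rec$log2FC < 0)
    rec$zRank <- NA_integer_
    rec$exprRank <- NA_integer_
    topZ <- list(); topE <- list()
    for (g in c("H", "L")) {
        sel <- which(rec$isMatch & rec$group == g)
        if (length(sel)) {
            rec$zRank[sel] <- denseRank(abs(rec$z[sel]))
            rec$exprRank[sel] <- denseRank(abs(rec$log2FC[sel]))
            ordZ <- sel[order(rec$zRank[sel], rec$ortholog[sel])]
            ordE <- sel[order(rec$exprRank[sel], rec$ortholog[sel])]
            topZ[[g]] <- rec$ortholog[utils::head(ordZ, topK)]
            topE[[g]] <- rec$ortholog[utils::head(ordE, topK)]
        } else {
            topZ[[g]] <- character()
            topE[[g]] <- character()
        }
    }
    rownames(rec) <- NULL
    list(records = rec, topByZ = topZ, topByExpression = topE,
         summary = list(
             nSignificant = nrow(rec),
             nDropped = dropped,
             nMajor = sum(rec$isMajor),
             nMatch = sum(rec$isMatch),
             nMatchByGroup = c(H = sum(rec$isMatch & rec$group == "H"),
                               L = sum(rec$isMatch & rec$group == "L"))))
}

#' Functional Effects Group (FE_g) score and two-group proportion test
#'
#' For each function, genes are binned by their enhanced group (H or L) and
#' by the annotated effect of their enhanced expression on the function
#' (\code{increases}, \code{decreases}, \code{affects}). The group score is
#' FE_g = (n_increase - n_decrease) / (n_increase + n_decrease + n_affect),
#' bounded in [-1, 1], and the two groups' category proportions are compared
#' with a G-test on the groups-by-categories table (columns empty in both
#' groups dropped; Fisher's exact test when any expected cell is below 1).
#' A group's direction call is \code{increased}/\code{decreased} when its
#' score is positive/negative and the test rejects at \code{alpha}, else
#' \code{indeterminate}.
#'
#' @param assoc data.frame with columns \code{ortholog}, \code{functionID},
#'   \code{effect} in \{increases, decreases, affects\}.
#' @param directions named character vector: gene/orthologue ID ->
#'   enhanced group; genes not covered are skipped with a message.
#' @param alpha significance level for the direction calls (default 0.05).
#' @param groups the two group labels (default \code{c("H", "L")}).
#' @return data.frame, one row per function: per-group category counts,
#'   FE scores, test statistic and p, test used, and direction calls.
#'   Functions with zero covered genes in both groups carry NA score and p.
#' @examples
#' assoc <- data.frame(
#'     ortholog = paste0("o", 1:20), functionID = "F1",
#'     effect = rep(c("increases", "decreases"), times = c(10, 10)))
#' dirs <- setNames(rep(c("H", "L"), each = 10), paste0("o", c(1:8, 19:20,
#'                                                             9:18)))
#' computeFEG(assoc, dirs)
#' @export
computeFEG <- function(assoc, directions, alpha = 0.05,
                       groups = c("H", "L")) {
    if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
        alpha <= 0 || alpha >= 1)
        stop("alpha must lie strictly between 0 and 1")
    effects <- c("increases", "decreases", "affects")
    bad <- setdiff(unique(assoc$effect), effects)
    if (length(bad))
        stop("unknown effect label(s): ", paste(bad, collapse = ", "))
    covered <- assoc$ortholog %in% names(directions)[!is.na(directions)]
    if (any(!covered))
        message(sum(!covered), " association(s) without a direction skipped")
    assoc <- assoc[covered, , drop = FALSE]
    grp <- directions[assoc$ortholog]

    feg <- function(cnt) {
        tot <- sum(cnt)
        if (tot == 0) NA_real_
        else (cnt["increases"] - cnt["decreases"]) / tot
    }
    out <- lapply(sort(unique(assoc$functionID)), function(f) {
        sel <- assoc$functionID == f
        cnts <- lapply(groups, function(g)
            table(factor(assoc$effect[sel & grp == g], levels = effects)))
        names(cnts) <- groups
        m <- do.call(rbind, cnts)                    # groups x categories
        m <- m[, colSums(m) > 0, drop = FALSE]
        tot <- rowSums(m)
        stat <- NA_real_; p <- NA_real_; test <- NA_character_
        if (all(tot > 0) && ncol(m) >= 2L) {
            E <- outer(rowSums(m), colSums(m)) / sum(m)
            if (any(E < 1)) {
                ft <- stats::fisher.test(m)
                p <- ft$p.value; test <- "fisher"
            } else {
                gt <- gStatistic(t(m))
                stat <- gt$G; p <- gt$p; test <- "G"
            }
        }
        s1 <- feg(cnts[[1]]); s2 <- feg(cnts[[2]])
        call1 <- if (is.na(s1) || is.na(p) || p > alpha || s1 == 0)
            "indeterminate" else if (s1 > 0) "increased" else "decreased"
        call2 <- if (is.na(s2) || is.na(p) || p > alpha || s2 == 0)
            "indeterminate" else if (s2 > 0) "increased" else "decreased"
        data.frame(functionID = f,
                   nInc1 = cnts[[1]]["increases"], nDec1 = cnts[[1]]["decreases"],
                   nAff1 = cnts[[1]]["affects"],
                   nInc2 = cnts[[2]]["increases"], nDec2 = cnts[[2]]["decreases"],
                   nAff2 = cnts[[2]]["affects"],
                   score1 = unname(s1), score2 = unname(s2),
                   statistic = stat, pvalue = p, test = test,
                   call1 = call1, call2 = call2, row.names = NULL)
    })
    res <- do.call(rbind, out)
    if (is.null(res))
        res <- data.frame(functionID = character())
    else {
        i <- c(2:7, 8:9, 13:14)
        names(res)[i] <- c(
            paste0(c("nInc_", "nDec_", "nAff_"), groups[1]),
            paste0(c("nInc_", "nDec_", "nAff_"), groups[2]),
            paste0("FE_", groups), paste0("call_", groups))
    }
    attr(res, "alpha") <- alpha
    res
}
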