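#' Normalize binary functional-impact calls
#'
#' Maps common spellings onto the canonical vocabulary
#' `"affected"`/`"unaffected"`/`"tie"`/`NA`: yes/damaging/deleterious/
#' disease_causing -> affected; no/tolerated/neutral/polymorphism ->
#' unaffected.
#'
#' @param x character vector of calls.
#' @return Character vector over `{"affected","unaffected","tie",NA}`.
#' @export
normalize_call <- function(x) {
  lx <- tolower(trimws(as.character(x)))
  out <- rep(NA_character_, length(x))
  out[lx %in% c("affected", "yes", "damaging", "deleterious", "disease causing",
                "disease_causing")] <- "affected"
  out[lx %in% c("unaffected", "no", "tolerated", "neutral", "polymorphism")] <- "unaffected"
  out[lx %in% c("tie", "ambiguous", "possibly affected", "yes/no")] <- "tie"
  bad <- !is.na(x) & lx != "" & lx != "na" & is.na(out)
  if (any(bad)) stop("unrecognized call value(s): ", paste(unique(x[bad]), collapse = ", "))
  out
}

#' Combined score over four binary predictor calls
#'
#' Sum of +1 per `"unaffected"` (tolerated) and -1 per `"affected"`
#' (deleterious) call, so the score lies in \{-4, -2, 0, +2, +4\};
#' negative scores call the variant affected, positive unaffected, and
#' zero is a tie. `NA` among the four calls gives an `NA` score.
#'
#' @param calls character vector of exactly 4 binary calls.
#' @return List with `score` (integer or NA) and `call`
#'   (`"affected"`, `"unaffected"`, `"tie"` or `NA`).
#' @export
combined_score <- function(calls) {
  if (length(calls) != 4L) stop("exactly 4 predictor calls required")
  calls <- normalize_call(calls)
  if (anyNA(calls) || any(calls == "tie"))
    return(list(score = NA_integer_, call = NA_character_))
  score <- sum(ifelse(calls == "unaffected", 1L, -1L))
  call <- if (score < 0L) "affected" else if (score > 0L) "unaffected" else "tie"
  list(score = score, call = call)
}

#' Cohen's kappa for two aligned binary raters
#'
#' Items with a tie or `NA` in either vector are excluded (pairwise
#' complete). With confusion counts a (both affected), b (first rater
#' only), c (second rater only), d (both unaffected) and n = a+b+c+d:
#' po = (a+d)/n, pe = ((a+b)(a+c) + (c+d)(b+d))/n^2, and
#' kappa = (po - pe)/(1 - pe). When n < 2 or pe = 1 (a constant pair)
#' kappa is undefined and flagged.
#'
#' @param calls_a,calls_b character vectors of calls (normalized via
#'   [normalize_call()]).
#' @return A `kappa_result`: list with `a`, `b`, `c`, `d`, `n`, `po`,
#'   `pe`, `kappa`, `undefined`.
#' @export
cohen_kappa <- function(calls_a, calls_b) {
  if (length(calls_a) != length(calls_b)) stop("call vectors differ in length")
  x <- normalize_call(calls_a); y <- normalize_call(calls_b)
  keep <- x %in% c("affected", "unaffected") & y %in% c("affected", "unaffected")
  x <- x[keep]; y <- y[keep]
  a <- sum(x == "affected" & y == "affected")
  b <- sum(x == "affected" & y == "unaffected")
  c_ <- sum(x == "unaffected" & y == "affected")
  d <- sum(x == "unaffected" & y == "unaffected")
  n <- a + b + c_ + d
  res <- list(a = a, b = b, c = c_, d = d, n = n,
              po = NA_real_, pe = NA_real_, kappa = NA_real_, undefined = TRUE)
  if (n >= 2L) {
    po <- (a + d) / n
    pe <- ((a + b) * (a + c_) + (c_ + d) * (b + d)) / n^2
    res$po <- po; res$pe <- pe
    if (pe < 1) {
      res$kappa <- (po - pe) / (1 - pe)
      res$undefined <- FALSE
    }
  }
  class(res) <- "kappa_result"
  res
}

#' @export
print.kappa_result <- function(x, ...) {
  cat("Cohen's kappa: ",
      if (x$undefined) "undefined" else format(round_half_up(x$kappa, 3L), nsmall = 3L),
      "  (n = ", x$n, "; a,b,c,d = ", x$a, ",", x$b, ",", x$c, ",", x$d, ")\n", sep = "")
  invisible(x)
}

#' Round half away from zero
#'
#' Agreement summaries are reported to 3 decimals with halves rounded
#' away from zero (the convention of the benchmark tables), unlike
#' [base::round()]'s round-half-even.
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return Rounded numeric.
#' @export
round_half_up <- function(x, digits = 3L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Pairwise Cohen's kappa matrix across raters
#'
#' @param ct data frame or matrix, items x raters, of binary calls.
#' @return Symmetric matrix of pairwise kappa on pairwise-complete
#'   items; diagonal 1 by convention; `NA` where undefined.
#' @export
kappa_matrix <- function(ct) {
  ct <- as.data.frame(ct)
  raters <- names(ct)
  if (length(raters) < 2L) stop("need at least 2 raters")
  k <- diag(1, length(raters))
  dimnames(k) <- list(raters, raters)
  for (i in seq_along(raters)[-length(raters)])
    for (j in seq.int(i + 1L, length(raters))) {
      r <- cohen_kappa(ct[[i]], ct[[j]])
      k[i, j] <- k[j, i] <- if (r$undefined) NA_real_ else r$kappa
    }
  k
}

#' Experimental functional labels for the packaged OGG1 variant set
#'
#' Labels derived from biochemical characterization of the purified
#' variants: three clearly impaired, two with a mild/ambiguous effect,
#' eight indistinguishable from wild type. Variants that could not be
#' purified carry no label.
#'
#' @return Named character vector over
#'   `{"affected","unaffected","ambiguous"}`.
#' @export
ogg1_experimental_labels <- function() {
  c(I145M = "affected", G202C = "affected", V267M = "affected",
    R161W = "ambiguous", S292N = "ambiguous",
    E92D = "unaffected", H111R = "unaffected", S118F = "unaffected",
    R206C = "unaffected", Q226H = "unaffected", Q263H = "unaffected",
    T285M = "unaffected", P291Q = "unaffected")
}

#' Packaged OGG1 predictor call table
#'
#' The four sequence-based predictor calls (SIFT, FATHMM,
#' MutationTaster, PROVEAN) for the 20 sampled OGG1 somatic variants,
#' plus the experimental label where available.
#'
#' @return Data frame: `variant`, one column per predictor,
#'   `experimental`.
#' @export
ogg1_call_table <- function() {
  f <- system.file("extdata", "ogg1_calls.csv", package = "mdvar")
  utils::read.csv(f, stringsAsFactors = FALSE, na.strings = c("NA", ""))
}

#' Benchmark predictor calls against experimental labels
#'
#' Computes Cohen's kappa of each prediction method against the
#' experimental classification, per ambiguity scenario. The wild type
#' is included as an extra item (experimentally unaffected and
#' predicted unaffected by every method) unless disabled. The combined
#' four-predictor score is evaluated with ties excluded by default;
#' when `md_affected` is given, the combined score is additionally
#' augmented by -1 for membership in the MD-derived affected set and +1
#' otherwise (no ties can remain), and the MD set itself is scored as a
#' method.
#'
#' @param calls data frame with a `variant` column and one column of
#'   binary calls per method (any recognized spelling).
#' @param labels named character vector of experimental labels over
#'   `{"affected","unaffected","ambiguous"}`; items absent from it are
#'   not benchmarked.
#' @param scenarios named list; each element is a named character
#'   vector resolving every ambiguous item to `"affected"` or
#'   `"unaffected"`.
#' @param predictors columns of `calls` combined into the score
#'   (exactly 4); set `NULL` to skip the combined score.
#' @param md_affected optional character vector: variants called
#'   affected by the MD tree classification (the distal set).
#' @param include_wt include the wild-type pseudo-item (default TRUE,
#'   required to match the reference benchmark layout).
#' @param wt_label item name used for the wild type.
#' @param tie_policy how combined-score ties enter the kappa:
#'   `"exclude"` (default), `"affected"`, or `"unaffected"`.
#' @return Data frame: `scenario`, `method`, `kappa`, `kappa3`
#'   (3-decimal half-up rounding), `a`, `b`, `c`, `d`, `n`.
#' @export
benchmark <- function(calls, labels, scenarios,
                      predictors = c("SIFT", "FATHMM", "MutationTaster", "PROVEAN"),
                      md_affected = NULL, include_wt = TRUE, wt_label = "WT",
                      tie_policy = c("exclude", "affected", "unaffected")) {
  tie_policy <- match.arg(tie_policy)
  stopifnot("variant" %in% names(calls))
  if (!is.null(predictors)) {
    miss <- setdiff(predictors, names(calls))
    if (length(miss)) stop("predictor column(s) missing: ", paste(miss, collapse = ", "))
    if (length(predictors) != 4L) stop("the combined score needs exactly 4 predictors")
  }
  method_cols <- setdiff(names(calls), c("variant", "experimental"))
  items <- intersect(calls$variant, names(labels))
  if (length(items) == 0L) stop("no benchmarkable items (variants with labels)")
  tab <- calls[match(items, calls$variant), , drop = FALSE]
  if (include_wt) {
    if (!wt_label %in% tab$variant) {
      wt_row <- tab[1L, , drop = FALSE]
      wt_row[1L, ] <- NA
      wt_row$variant <- wt_label
      for (mcol in method_cols) wt_row[[mcol]] <- "unaffected"
      tab <- rbind(tab, wt_row)
      items <- c(items, wt_label)
    }
  } else {
    warning("benchmark computed without the wild-type item; ",
            "values are not comparable to the WT-inclusive layout")
  }
  lab_of <- function(scenario) {
    l <- labels[items]
    names(l) <- items
    if (include_wt) l[wt_label] <- "unaffected"
    amb <- names(l)[!is.na(l) & l == "ambiguous"]
    unresolved <- setdiff(amb, names(scenario))
    if (length(unresolved))
      stop("scenario leaves ambiguous item(s) unresolved: ",
           paste(unresolved, collapse = ", "))
    l[amb] <- scenario[amb]
    l
  }
  comb <- if (!is.null(predictors)) {
    apply(tab[, predictors, drop = FALSE], 1L, function(r) {
      cs <- combined_score(as.character(r))
      c(score = cs$score, call = cs$call)
    })
  } else NULL
  rows <- list()
  add <- function(scenario_name, method, calls_vec, l) {
    r <- cohen_kappa(calls_vec, unname(l))
    rows[[length(rows) + 1L]] <<- data.frame(
      scenario = scenario_name, method = method,
      kappa = r$kappa, kappa3 = round_half_up(r$kappa, 3L),
      a = r$a, b = r$b, c = r$c, d = r$d, n = r$n, stringsAsFactors = FALSE)
  }
  for (sc in names(scenarios)) {
    l <- lab_of(scenarios[[sc]])
    for (mcol in method_cols) add(sc, mcol, tab[[mcol]], l)
    if (!is.null(comb)) {
      cc <- unlist(comb["call", ])
      if (tie_policy != "exclude") cc[!is.na(cc) & cc == "tie"] <- tie_policy
      add(sc, "combined", cc, l)
      if (!is.null(md_affected)) {
        sc0 <- suppressWarnings(as.integer(comb["score", ]))
        aug <- sc0 + ifelse(tab$variant %in% md_affected, -1L, 1L)
        aug_call <- ifelse(aug < 0L, "affected", "unaffected")
        add(sc, "combined+md", aug_call, l)
      }
    }
    if (!is.null(md_affected)) {
      md_call <- ifelse(tab$variant %in% md_affected, "affected", "unaffected")
      add(sc, "md_distal", md_call, l)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
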