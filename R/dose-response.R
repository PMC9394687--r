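#' Normalized log-logistic viability model
#'
#' \code{response = bottom + (top - bottom) / (1 + 10^((x - logIc50) * hill))}
#' with \code{x = log10(concentration)}. The default normalized form fixes
#' top = 100 and bottom = 0 (percent viability relative to vehicle).
#'
#' @param conc concentrations (molar, > 0).
#' @param logIc50 log10 molar IC50.
#' @param hill Hill slope.
#' @param top,bottom asymptotes in percent.
#' @return predicted responses (percent).
#' @export
doseResponseModel <- function(conc, logIc50, hill, top = 100, bottom = 0) {
    bottom + (top - bottom) / (1 + 10^((log10(conc) - logIc50) * hill))
}

#' Normalize viability readings to vehicle
#'
#' Scales raw readings so the vehicle (e.g. DMSO) mean maps to 100 percent.
#' Normalization is per (compound, sample) curve and idempotent: applied a
#' second time the vehicle mean is already 100 and nothing changes.
#'
#' @param data data.frame in the viability-table layout: \code{compound},
#'   \code{sample}, \code{concentration_molar}, \code{replicate},
#'   \code{reading}, \code{is_vehicle} (logical).
#' @return the same data.frame with \code{reading} rescaled to percent.
#' @export
normalizeToVehicle <- function(data) {
    key <- paste(data$compound, data$sample, sep = "\r")
    out <- lapply(split(data, key), function(d) {
        veh <- d$reading[d$is_vehicle]
        if (!length(veh))
            stop("data error: no vehicle readings for ", d$compound[1L],
                 " / ", d$sample[1L])
        m <- mean(veh)
        if (!is.finite(m) || m <= 0)
            stop("data error: non-positive vehicle mean for ",
                 d$compound[1L], " / ", d$sample[1L])
        d$reading <- d$reading * 100 / m
        d
    })
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res[order(res$compound, res$sample, -res$concentration_molar,
              res$replicate), , drop = FALSE]
}

#' Fit the normalized log-logistic model to one curve
#'
#' Least squares on percent responses versus log10 concentration, top fixed
#' at 100 and bottom at 0 (set \code{fixedAsymptotes = FALSE} for the
#' 4-parameter variant). Initialization puts \code{logIc50} at the
#' concentration whose mean response is nearest 50 percent and the Hill
#' slope at 1. Standard errors come from the curvature (information)
#' approximation of the objective. Failure to converge, a non-positive
#' fitted slope, an IC50 outside [min conc / 100, max conc x 100], or a
#' non-responsive curve (fitted dynamic range under 25 percent across the
#' tested concentrations, i.e. flat within noise) mark the fit
#' \code{converged = FALSE}; no exception is thrown for degenerate data.
#'
#' @param conc concentrations in molar units (>= 4 distinct values).
#' @param response normalized responses in percent (same length).
#' @param compound,sample labels stored in the fit.
#' @param fixedAsymptotes fix top = 100, bottom = 0 (default TRUE).
#' @return A \linkS4class{DoseResponseFit}.
#' @examples
#' conc <- designDilutionSeries(50e-6, 15, minConc = 1.58e-9)
#' y <- doseResponseModel(conc, log10(1e-6), 1)
#' ic50(fitDoseResponse(conc, y))   # 1e-6
#' @export
fitDoseResponse <- function(conc, response, compound = NA_character_,
                            sample = NA_character_, fixedAsymptotes = TRUE) {
    if (length(conc) != length(response))
        stop("conc and response lengths differ")
    if (any(conc <= 0))
        stop("concentrations must be positive")
    if (length(unique(conc)) < 4L)
        stop("input error: need at least 4 distinct concentrations")
    x <- log10(conc)
    meanByConc <- tapply(response, x, mean)
    start50 <- as.numeric(names(meanByConc)[
        which.min(abs(meanByConc - 50))])
    fail <- function() new("DoseResponseFit", compound = compound,
                           sample = sample, logIc50 = NA_real_,
                           hill = NA_real_, top = 100, bottom = 0,
                           seLogIc50 = NA_real_, seHill = NA_real_,
                           converged = FALSE, n = length(response))
    fit <- tryCatch({
        if (fixedAsymptotes) {
            minpack.lm::nlsLM(
                response ~ 100 / (1 + 10^((x - logIc50) * hill)),
                start = list(logIc50 = start50, hill = 1),
                control = minpack.lm::nls.lm.control(maxiter = 200))
        } else {
            minpack.lm::nlsLM(
                response ~ bottom + (top - bottom) /
                    (1 + 10^((x - logIc50) * hill)),
                start = list(logIc50 = start50, hill = 1, top = 100,
                             bottom = 0),
                control = minpack.lm::nls.lm.control(maxiter = 200))
        }
    }, error = function(e) NULL)
    if (is.null(fit)) return(fail())
    est <- stats::coef(fit)
    se <- tryCatch(sqrt(diag(stats::vcov(fit))),
                   error = function(e) rep(NA_real_, length(est)))
    ic50 <- 10^est[["logIc50"]]
    yhat <- stats::predict(fit)
    responsive <- (max(yhat) - min(yhat)) >= 25  # flat within noise fails
    ok <- is.finite(est[["logIc50"]]) && is.finite(est[["hill"]]) &&
        est[["hill"]] > 0 && responsive &&
        ic50 >= min(conc) / 100 && ic50 <= max(conc) * 100
    new("DoseResponseFit", compound = compound, sample = sample,
        logIc50 = unname(est[["logIc50"]]), hill = unname(est[["hill"]]),
        top = if (fixedAsymptotes) 100 else unname(est[["top"]]),
        bottom = if (fixedAsymptotes) 0 else unname(est[["bottom"]]),
        seLogIc50 = unname(se[1L]), seHill = unname(se[2L]),
        converged = ok, n = length(response))
}

#' @rdname DoseResponseFit-class
#' @param x a \code{DoseResponseFit}.
#' @export
ic50 <- function(x) 10^x@logIc50

#' @rdname DoseResponseFit-class
#' @export
hillSlope <- function(x) x@hill

#' @rdname DoseResponseFit-class
#' @export
isConverged <- function(x) x@converged

setMethod("show", "DoseResponseFit", function(object) {
    if (!object@converged) {
        cat("DoseResponseFit (not converged)\n")
        return(invisible(NULL))
    }
    cat(sprintf(
        "DoseResponseFit%s%s: IC50 = %s M (logIC50 %.3f +/- %.3f), Hill = %.2f +/- %.2f, n = %d\n",
        if (is.na(object@compound)) "" else paste0(" ", object@compound),
        if (is.na(object@sample)) "" else paste0(" / ", object@sample),
        format(10^object@logIc50, digits = 3), object@logIc50,
        object@seLogIc50, object@hill, object@seHill, object@n))
})

#' Fold-resistance between two fitted curves
#'
#' Ratio of mutant to parental IC50 for the same compound; > 1 means the
#' mutant requires more compound for half-maximal inhibition. Unit-invariant
#' (any common rescaling of concentrations cancels).
#'
#' @param mutant,parental converged \linkS4class{DoseResponseFit}s.
#' @return positive numeric ratio.
#' @examples
#' # enantiomer potency ratio from printed IC50s (14.57 uM vs 0.26 uM)
#' f <- function(x) new("DoseResponseFit", compound = "c", sample = "s",
#'                      logIc50 = log10(x), hill = 1, top = 100, bottom = 0,
#'                      seLogIc50 = 0, seHill = 0, converged = TRUE, n = 30L)
#' signif(foldResistance(f(14.57e-6), f(0.26e-6)), 2)  # 56
#' @export
foldResistance <- function(mutant, parental) {
    if (!isConverged(mutant) || !isConverged(parental))
        stop("fold-resistance requires converged fits")
    10^(mutant@logIc50 - parental@logIc50)
}

#' Geometric dilution series for a dose-response plate
#'
#' Descending geometric series from \code{maxConc}; give exactly one of
#' \code{ratio} (fold between adjacent points) or \code{minConc} (the ratio
#' is then \code{(max/min)^(1/(n-1))} so the last point equals
#' \code{minConc}).
#'
#' @param maxConc top concentration (molar).
#' @param nPoints number of points (>= 2).
#' @param ratio fold-dilution between adjacent points.
#' @param minConc bottom concentration (molar).
#' @return numeric vector of length \code{nPoints}, descending.
#' @examples
#' designDilutionSeries(50e-6, 15, minConc = 1.58e-9)  # assay design
#' designDilutionSeries(50e-6, 10, ratio = 2)[6]       # 1.5625e-06
#' @export
designDilutionSeries <- function(maxConc, nPoints, ratio = NULL,
                                 minConc = NULL) {
    if (is.null(ratio) == is.null(minConc))
        stop("give exactly one of ratio or minConc")
    if (nPoints < 2L) stop("input error: nPoints must be >= 2")
    if (maxConc <= 0 || (!is.null(ratio) && ratio <= 0) ||
        (!is.null(minConc) && minConc <= 0))
        stop("input error: concentrations and ratio must be positive")
    if (is.null(ratio)) ratio <- (maxConc / minConc)^(1 / (nPoints - 1))
    maxConc / ratio^(seq_len(nPoints) - 1)
}

#' Screen concentration bracket around the one-week IC100
#'
#' The three selection concentrations used in the forward-genetic screen:
#' the minimum concentration leaving no viable cells after one week
#' (IC100^1wk), bracketed by dividing and multiplying by 1.25. Reported to
#' two decimals (concentrations in micromolar).
#'
#' @param ic100 IC100^1wk in micromolar.
#' @return named numeric vector \code{c(low, mid, high)}.
#' @examples
#' screenConcentrationBracket(0.98)  # 0.78 0.98 1.22
#' @export
screenConcentrationBracket <- function(ic100) {
    if (ic100 <= 0) stop("ic100 must be positive")
    roundDecimal(c(low = ic100 / 1.25, mid = ic100, high = ic100 * 1.25), 2L)
}

# decimal-correct round-half-even: 0.98 * 1.25 = 1.225 must report as 1.22
# even though its binary representation sits just above the midpoint
roundDecimal <- function(x, digits) {
    m <- x * 10^digits
    f <- m - floor(m)
    half <- abs(f - 0.5) < 1e-9
    r <- ifelse(half,
                ifelse(floor(m) %% 2 == 0, floor(m), floor(m) + 1),
                round(m))
    r / 10^digits
}

#' Read a viability table
#'
#' CSV or TSV (by extension) with columns \code{compound}, \code{sample},
#' \code{concentration_molar}, \code{replicate}, \code{reading},
#' \code{is_vehicle}.
#'
#' @param path input file.
#' @return data.frame.
#' @export
readViabilityTable <- function(path) {
    sep <- if (grepl("\\.tsv$|\\.txt$", path)) "\t" else ","
    tab <- utils::read.table(path, header = TRUE, sep = sep,
                             stringsAsFactors = FALSE)
    need <- c("compound", "sample", "concentration_molar", "replicate",
              "reading", "is_vehicle")
    if (!all(need %in% names(tab)))
        stop("viability table must have columns: ",
             paste(need, collapse = ", "))
    tab$is_vehicle <- as.logical(tab$is_vehicle)
    tab
}
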