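#' Read / write longitudinal PK datasets (NONMEM-style CSV)
#'
#' Columns: `ID`, `TIME` (h), `EVID` (1 = dose, 0 = observation), `AMT` (mg),
#' `DUR` (infusion duration, h; alternatively `RATE` in mg/h), `DV` (observed
#' concentration, mg/L), `MDV`, plus covariate columns (`AGE`, `SEX`, `WT`,
#' `ALT`, `AST`, `TBIL`, `DBIL`, `ALB`, `CRCL`, ...). Missing values are
#' written as `.`.
#'
#' @param path file path.
#' @param data a data.frame in the layout above.
#' @return `read_pkdata()` returns a validated data.frame.
#' @export
read_pkdata <- function(path) {
  d <- utils::read.csv(path, na.strings = c(".", "NA", ""))
  validate_pkdata(d)
}

#' @rdname read_pkdata
#' @export
write_pkdata <- function(data, path) {
  d <- validate_pkdata(data)
  utils::write.csv(format_pkdata(d), path, row.names = FALSE, quote = FALSE,
                   na = ".")
  invisible(path)
}

format_pkdata <- function(d) {
  num <- vapply(d, is.numeric, logical(1))
  d[num] <- lapply(d[num], function(x) {
    ifelse(is.na(x), NA, formatC(x, format = "g", digits = 10))
  })
  d
}

validate_pkdata <- function(d) {
  need <- c("ID", "TIME", "EVID", "AMT", "DV")
  check_that(all(need %in% names(d)),
             paste("dataset must contain columns:", paste(need, collapse = ", ")))
  if (is.null(d$MDV)) d$MDV <- ifelse(d$EVID == 0, 0, 1)
  if (is.null(d$DUR)) {
    check_that(!is.null(d$RATE), "dataset needs a DUR or RATE column")
    d$DUR <- ifelse(d$EVID == 1 & d$RATE > 0, d$AMT / d$RATE, NA)
  }
  check_that(all(d$TIME >= 0, na.rm = TRUE), "TIME must be >= 0")
  obs <- d$EVID == 0 & d$MDV == 0
  check_that(all(d$DV[obs] > 0, na.rm = TRUE),
             "observed concentrations must be positive (log-scale likelihood)")
  d
}

## ---- internal: per-subject structure ------------------------------------
## Returns a list, one element per subject: id, obs (time, dv), events
## (start, amount, duration, rate), covs (time + covariate columns, LOCF
## track), tv (TRUE if any fitted covariate varies within the subject).
split_subjects <- function(data, covariates = character(0)) {
  d <- validate_pkdata(data)
  reserved <- c("ID", "TIME", "EVID", "AMT", "DUR", "RATE", "DV", "MDV")
  covcols <- union(covariates, setdiff(names(d), reserved))
  lapply(split(d, factor(d$ID, levels = unique(d$ID))), function(s) {
    s <- s[order(s$TIME), , drop = FALSE]
    dose <- s$EVID == 1 & s$AMT > 0
    obs <- s$EVID == 0 & s$MDV == 0
    covs <- s[, intersect(covcols, names(s)), drop = FALSE]
    ## LOCF within subject
    covs[] <- lapply(covs, function(x) {
      ok <- which(!is.na(x))
      if (!length(ok)) return(x)
      idx <- findInterval(seq_along(x), ok)
      x[ok[pmax(idx, 1L)]]
    })
    covs <- cbind(time = s$TIME, covs)
    list(id = s$ID[1], obs = data.frame(time = s$TIME[obs], dv = s$DV[obs]),
         events = data.frame(start = s$TIME[dose], amount = s$AMT[dose],
                             duration = s$DUR[dose],
                             rate = s$AMT[dose] / s$DUR[dose]),
         covs = covs)
  })
}

## covariate value(s) used for a subject: value at time t (LOCF)
cov_at <- function(covs, name, t) {
  x <- covs[[name]]
  if (is.null(x)) stop("missing covariate: ", name, call. = FALSE)
  i <- findInterval(t, covs$time)
  x[pmax(i, 1L)]
}
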