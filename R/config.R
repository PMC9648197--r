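# Plain-text run configuration (TOML dialect, subset: [tables], key = value
# with strings, numbers, booleans and flat arrays).

.parseTomlValue <- function(v) {
  v <- trimws(v)
  if (grepl("^\\[.*\\]$", v)) {
    parts <- strsplit(gsub("^\\[|\\]$", "", v), ",")[[1]]
    return(unlist(lapply(parts, .parseTomlValue)))
  }
  if (grepl('^".*"$', v) || grepl("^'.*'$", v)) return(gsub('^["\']|["\']$', "", v))
  if (v %in% c("true", "false")) return(v == "true")
  num <- suppressWarnings(as.numeric(v))
  if (!is.na(num)) return(num)
  v
}

#' Read a run configuration file
#'
#' TOML-dialect subset with the tables \code{[system]}, \code{[gw]},
#' \code{[bse]}, \code{[analysis]}.  Unknown keys are kept verbatim; every
#' threshold of \code{gwConfig} is a named key with the package default.
#'
#' @param path configuration file
#' @return nested named list
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  tab <- NULL
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      tab <- gsub("^\\[|\\]$", "", ln)
      out[[tab]] <- list()
    } else if (grepl("=", ln, fixed = TRUE)) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      key <- trimws(kv[1])
      val <- .parseTomlValue(paste(kv[-1], collapse = "="))
      if (is.null(tab)) out[[key]] <- val else out[[tab]][[key]] <- val
    } else {
      stop("cannot parse config line: ", ln, call. = FALSE)
    }
  }
  out
}

# merge a [gw]/[bse] config table onto gwConfig defaults
.configFrom <- function(cfgList) {
  args <- list()
  gw <- cfgList$gw
  map <- c(n_grid_points = "nGridPoints", eps_s = "epsS",
           evgw_conv_homo = "evgwConvHomo",
           qsgw_conv_density = "qsgwConvDensity", max_cycles = "maxCycles",
           mixing = "mixing", screening = "screening", accel = "accel")
  for (k in names(map)) if (!is.null(gw[[k]])) args[[map[k]]] <- gw[[k]]
  bse <- cfgList$bse
  mapB <- c(ph_cutoff = "phCutoff", davidson_tol = "davidsonTol",
            n_roots = "nRoots")
  for (k in names(mapB)) if (!is.null(bse[[k]])) args[[mapB[k]]] <- bse[[k]]
  do.call(gwConfig, args)
}
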