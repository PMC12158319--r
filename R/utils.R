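# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
cg_log <- function(..., level = "info") {
  if (isTRUE(getOption("courtgaze.quiet", FALSE)) && level == "info") {
    return(invisible(NULL))
  }
  message(sprintf("[courtgaze:%s] %s", level, paste0(...)))
  invisible(NULL)
}

cg_warn <- function(...) warning(paste0(...), call. = FALSE)

cg_stop <- function(...) stop(sprintf(...), call. = FALSE)

#' Evaluate an expression under a fixed RNG seed, restoring RNG state after
#' @noRd
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Nearest-neighbor lookup of sorted reference timestamps.
# Returns for each query the index into `ref` minimizing |ref - query|;
# ties in |delta| are broken toward the earlier (lower-index) sample.
nearest_index <- function(query, ref) {
  if (length(ref) == 0L) return(rep(NA_integer_, length(query)))
  lo <- findInterval(query, ref)          # ref[lo] <= q < ref[lo+1]
  lo[lo < 1L] <- 1L
  hi <- pmin(lo + 1L, length(ref))
  d_lo <- abs(query - ref[lo])
  d_hi <- abs(query - ref[hi])
  ifelse(d_lo <= d_hi, lo, hi)            # <= : earlier sample wins ties
}

# Deterministic plain-text CSV writer: each column is formatted with an
# explicit sprintf format so identical data always produce identical bytes.
write_csv_formatted <- function(df, path, formats) {
  stopifnot(identical(names(formats), names(df)))
  out <- vapply(names(df), function(nm) {
    col <- df[[nm]]
    fmt <- formats[[nm]]
    if (identical(fmt, "s")) as.character(col) else {
      v <- sprintf(fmt, col)
      v[is.na(col)] <- ""
      v
    }
  }, character(nrow(df)))
  if (nrow(df) == 1L) out <- matrix(out, nrow = 1L, dimnames = list(NULL, names(df)))
  if (nrow(df) == 0L) {
    lines <- paste(names(df), collapse = ",")
  } else {
    lines <- c(paste(names(df), collapse = ","),
               apply(out, 1L, paste, collapse = ","))
  }
  writeLines(lines, path)
  invisible(path)
}

# format spec constants for the export dialect
FMT_TS <- "%.0f"      # integer nanoseconds
FMT_REAL <- "%.10f"   # round-trips to well under 1e-9 at pixel/mm scales
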