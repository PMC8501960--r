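# Plain-text interchange: 3DNA-style base-pair-step parameter files and
# repression-level CSV tables.

#' Read and write base-pair-step parameter files
#'
#' The 3DNA-style `.par` step dialect: a header line naming the columns in
#' the order `shift slide rise tilt roll twist`, then one whitespace-
#' separated numeric row per step.  Round trips are lossless at six
#' decimal places.
#'
#' @param path file path.
#' @return `read_par()`: an n x 6 step matrix in the package's canonical
#'   order (tilt, roll, twist, shift, slide, rise).
#' @export
read_par <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) < 2)
    stop("par file has no step rows: ", path, call. = FALSE)
  body <- lines[-1]
  rows <- lapply(seq_along(body), function(i) {
    f <- strsplit(trimws(body[i]), "\\s+")[[1]]
    v <- suppressWarnings(as.numeric(f))
    if (length(v) != 6 || any(is.na(v)))
      stop(sprintf("par parse error at line %d: need 6 numeric columns",
                   i + 1), call. = FALSE)
    v
  })
  m <- do.call(rbind, rows)
  # file order shift slide rise tilt roll twist -> canonical order
  as_step_matrix(m[, c(4, 5, 6, 1, 2, 3), drop = FALSE])
}

#' @rdname read_par
#' @param steps n x 6 step matrix (canonical order) or a
#'   [protein_footprint()].
#' @export
write_par <- function(steps, path) {
  if (inherits(steps, "protein_footprint")) steps <- steps$steps
  steps <- as_step_matrix(steps)
  out <- steps[, c("shift", "slide", "rise", "tilt", "roll", "twist"),
               drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("   shift    slide     rise     tilt     roll    twist", con)
  writeLines(apply(out, 1, function(r) paste(sprintf("%9.6f", r),
                                             collapse = " ")), con)
  invisible(path)
}

#' Read and write repression-level tables
#'
#' CSV with columns `series, condition, spacing, RL, sd, n`; validation
#' enforces positive RL and unique spacings on load.
#'
#' @param path file path.
#' @return `read_rl_table()`: a validated `rl_data` data frame; the
#'   `rl_noloop` attribute is taken from an `rl_noloop` column if present
#'   (constant per file).
#' @export
read_rl_table <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("spacing", "RL")
  if (!all(need %in% names(d)))
    stop("RL table needs at least columns 'spacing' and 'RL'",
         call. = FALSE)
  bad <- which(d$RL <= 0)
  if (length(bad))
    stop("nonpositive RL in rows: ", paste(bad, collapse = ", "),
         call. = FALSE)
  dup <- which(duplicated(d$spacing))
  if (length(dup))
    stop("duplicate spacing in rows: ", paste(dup, collapse = ", "),
         call. = FALSE)
  if ("rl_noloop" %in% names(d)) {
    attr(d, "rl_noloop") <- d$rl_noloop[1]
    d$rl_noloop <- NULL
  }
  class(d) <- c("rl_data", "data.frame")
  d
}

#' @rdname read_rl_table
#' @param data an `rl_data` data frame (e.g. from [generate_rl_dataset()]).
#' @export
write_rl_table <- function(data, path) {
  d <- as.data.frame(data)
  if (!is.null(attr(data, "rl_noloop"))) d$rl_noloop <- attr(data, "rl_noloop")
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}
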