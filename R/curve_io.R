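#' Construct a 2D suture curve
#'
#' A `curve2d` is an ordered open polyline of digitised suture points for a
#' single specimen. Consecutive duplicate points (zero-length segments) are
#' dropped with a warning, since they carry no geometric information and break
#' arc-length interpolation.
#'
#' @param specimen_id Single character label for the specimen.
#' @param points Numeric matrix with two columns (x, y) and at least two rows,
#'   ordered along the suture.
#' @param closed Logical; suture traces are open polylines, so this is always
#'   `FALSE`.
#' @return An object of class `curve2d` with elements `specimen_id`, `points`
#'   and `closed`.
#' @examples
#' curve2d("sp001", cbind(x = 0:2, y = c(0, 1, 0)))
#' @export
curve2d <- function(specimen_id, points, closed = FALSE) {
  if (!is.character(specimen_id) || length(specimen_id) != 1L ||
      is.na(specimen_id) || !nzchar(specimen_id)) {
    stop_validation("`specimen_id` must be a single non-empty string")
  }
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (ncol(points) != 2L) {
    stop_validation("`points` must have exactly two columns (x, y)")
  }
  if (!all(is.finite(points))) {
    stop_validation(sprintf("curve '%s' contains non-finite coordinates",
                            specimen_id))
  }
  if (nrow(points) >= 2L) {
    dup <- c(FALSE, segment_lengths(points) == 0)
    if (any(dup)) {
      warning(sprintf("curve '%s': dropped %d consecutive duplicate point(s)",
                      specimen_id, sum(dup)), call. = FALSE)
      points <- points[!dup, , drop = FALSE]
    }
  }
  if (nrow(points) < 2L) {
    stop_validation(sprintf("curve '%s' must have at least 2 distinct points",
                            specimen_id))
  }
  if (!identical(closed, FALSE)) {
    stop_validation("only open curves (`closed = FALSE`) are supported")
  }
  dimnames(points) <- list(NULL, c("x", "y"))
  structure(list(specimen_id = specimen_id, points = points, closed = FALSE),
            class = "curve2d")
}

#' @export
print.curve2d <- function(x, ...) {
  cat(sprintf("<%s> specimen '%s': %d points\n",
              paste(class(x), collapse = "/"), x$specimen_id, nrow(x$points)))
  invisible(x)
}

#' Read 2D suture curves from a CSV or TPS file
#'
#' The CSV dialect has the header `specimen_id,point_index,x,y`; rows are
#' grouped by specimen and ordered by `point_index`. The TPS dialect consists
#' of records with an `LM=k` count line, `k` whitespace-separated coordinate
#' lines and an `ID=label` line; other TPS keywords (`IMAGE=`, `SCALE=`, ...)
#' are ignored with a warning.
#'
#' @param path Path to the input file.
#' @param format Either `"csv"` or `"tps"`.
#' @param flip_y If `TRUE`, negate the y coordinates on input. Use this for
#'   sources digitised in image convention (y increasing downwards); the
#'   internal convention is y increasing upwards.
#' @return A list of [curve2d] objects, one per specimen, in file order.
#' @seealso [write_curves()], [resample_equidistant()]
#' @export
read_curves <- function(path, format = c("csv", "tps"), flip_y = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop_validation(sprintf("file not found: '%s'", path))
  }
  curves <- switch(format,
                   csv = read_curves_csv(path),
                   tps = read_curves_tps(path))
  if (length(curves) == 0L) {
    stop_validation(sprintf("'%s': no curve records found", path))
  }
  ids <- vapply(curves, function(cv) cv$specimen_id, character(1))
  if (anyDuplicated(ids)) {
    stop_validation(sprintf("duplicate specimen_id(s): %s",
                            paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  if (flip_y) {
    curves <- lapply(curves, function(cv) {
      cv$points[, 2] <- -cv$points[, 2]
      cv
    })
  }
  curves
}

read_curves_csv <- function(path) {
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE),
    error = function(e) {
      stop_validation(sprintf("'%s': cannot parse as CSV: %s",
                              path, conditionMessage(e)))
    })
  required <- c("specimen_id", "point_index", "x", "y")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop_validation(sprintf("'%s': missing required column(s): %s",
                            path, paste(missing_cols, collapse = ", ")))
  }
  if (nrow(df) == 0L) {
    stop_validation(sprintf("'%s': no curve records found", path))
  }
  if (!is.numeric(df$x) || !is.numeric(df$y) || !is.numeric(df$point_index)) {
    bad <- which(is.na(suppressWarnings(as.numeric(df$x))) |
                   is.na(suppressWarnings(as.numeric(df$y))))[1]
    stop_validation(sprintf("'%s': non-numeric coordinate near data line %d",
                            path, if (length(bad)) bad else 1L))
  }
  ids <- unique(df$specimen_id)
  lapply(ids, function(id) {
    rec <- df[df$specimen_id == id, , drop = FALSE]
    if (anyDuplicated(rec$point_index)) {
      stop_validation(sprintf("'%s': specimen '%s' has duplicated point_index",
                              path, id))
    }
    rec <- rec[order(rec$point_index), , drop = FALSE]
    if (nrow(rec) < 2L) {
      stop_validation(sprintf("'%s': specimen '%s' has fewer than 2 points",
                              path, id))
    }
    curve2d(as.character(id), cbind(rec$x, rec$y))
  })
}

read_curves_tps <- function(path) {
  lines <- readLines(path, warn = FALSE)
  curves <- list()
  i <- 1L
  n_lines <- length(lines)
  while (i <= n_lines) {
    line <- trimws(lines[i])
    if (!nzchar(line)) {
      i <- i + 1L
      next
    }
    if (!grepl("^LM\\s*=", line, ignore.case = TRUE)) {
      stop_validation(sprintf("'%s' line %d: expected 'LM=' record start, got '%s'",
                              path, i, line))
    }
    k <- suppressWarnings(as.integer(sub("^LM\\s*=\\s*", "", line,
                                         ignore.case = TRUE)))
    if (is.na(k) || k < 2L) {
      stop_validation(sprintf("'%s' line %d: invalid landmark count (need >= 2)",
                              path, i))
    }
    if (i + k > n_lines) {
      stop_validation(sprintf("'%s' line %d: record declares %d landmarks but file ends early",
                              path, i, k))
    }
    coord_lines <- lines[(i + 1L):(i + k)]
    coords <- t(vapply(seq_along(coord_lines), function(j) {
      vals <- suppressWarnings(as.numeric(strsplit(trimws(coord_lines[j]),
                                                   "\\s+")[[1]]))
      if (length(vals) != 2L || anyNA(vals)) {
        stop_validation(sprintf("'%s' line %d: expected two numeric coordinates",
                                path, i + j))
      }
      vals
    }, numeric(2)))
    i <- i + k + 1L
    id <- NULL
    while (i <= n_lines) {
      line <- trimws(lines[i])
      if (!nzchar(line)) {
        i <- i + 1L
        next
      }
      if (grepl("^ID\\s*=", line, ignore.case = TRUE)) {
        id <- sub("^ID\\s*=\\s*", "", line, ignore.case = TRUE)
        i <- i + 1L
        break
      }
      if (grepl("^LM\\s*=", line, ignore.case = TRUE)) break
      warning(sprintf("'%s' line %d: ignoring TPS keyword '%s'",
                      path, i, sub("=.*$", "", line)), call. = FALSE)
      i <- i + 1L
    }
    if (is.null(id)) {
      id <- sprintf("record_%03d", length(curves) + 1L)
    }
    curves[[length(curves) + 1L]] <- curve2d(id, coords)
  }
  curves
}

#' Write 2D suture curves to a CSV or TPS file
#'
#' @param curves List of [curve2d] objects.
#' @param path Output file path.
#' @param format Either `"csv"` or `"tps"`; dialects as in [read_curves()].
#' @return Invisibly, `path`.
#' @export
write_curves <- function(curves, path, format = c("csv", "tps")) {
  format <- match.arg(format)
  if (inherits(curves, "curve2d")) curves <- list(curves)
  stopifnot(length(curves) > 0L,
            all(vapply(curves, inherits, logical(1), "curve2d")))
  if (format == "csv") {
    df <- do.call(rbind, lapply(curves, function(cv) {
      data.frame(specimen_id = cv$specimen_id,
                 point_index = seq_len(nrow(cv$points)),
                 x = cv$points[, 1], y = cv$points[, 2])
    }))
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    for (cv in curves) {
      writeLines(sprintf("LM=%d", nrow(cv$points)), con)
      writeLines(sprintf("%.12g %.12g", cv$points[, 1], cv$points[, 2]), con)
      writeLines(sprintf("ID=%s", cv$specimen_id), con)
    }
  }
  invisible(path)
}

#' Resample a curve to equidistant semi-landmarks
#'
#' Places `n` points at arc-length positions `k * L / (n - 1)`,
#' `k = 0, ..., n - 1`, along the source polyline (`L` = total chord length),
#' located by linear interpolation on the cumulative chord-length
#' parameterisation. The endpoints of the source curve are preserved exactly.
#' This is the standard equidistant semi-landmark scheme used to put a varying
#' number of digitised suture points on a common basis (250 per suture in the
#' study design this package supports).
#'
#' @param curve A [curve2d].
#' @param n Number of output points (>= 2); default 250.
#' @return A `resampled_curve2d` (also a `curve2d`) with element `n`.
#' @examples
#' cv <- curve2d("s1", cbind(c(0, 1, 1), c(0, 0, 1)))
#' resample_equidistant(cv, 3)$points
#' @export
resample_equidistant <- function(curve, n = 250L) {
  stopifnot(inherits(curve, "curve2d"))
  if (!is.numeric(n) || length(n) != 1L || n != round(n) || n < 2) {
    stop_validation("`n` must be a single integer >= 2")
  }
  n <- as.integer(n)
  pts <- curve$points
  seg <- segment_lengths(pts)
  L <- sum(seg)
  if (L <= 0) {
    stop_validation(sprintf("curve '%s' has zero length", curve$specimen_id))
  }
  cum <- c(0, cumsum(seg))
  target <- seq(0, L, length.out = n)
  out <- cbind(
    stats::approx(cum, pts[, 1], xout = target, ties = "ordered")$y,
    stats::approx(cum, pts[, 2], xout = target, ties = "ordered")$y
  )
  out[1, ] <- pts[1, ]
  out[n, ] <- pts[nrow(pts), ]
  res <- curve2d(curve$specimen_id, out)
  res$n <- n
  class(res) <- c("resampled_curve2d", class(res))
  res
}
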