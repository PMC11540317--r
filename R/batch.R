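result_error_row <- function(file, message) {
  tibble(
    file = file,
    ODI_D = NA_real_, ODI_A = NA_real_, ODI = NA_real_,
    Z = NA_integer_, P = NA_real_, N_used = NA_integer_,
    error = message
  )
}

#' Analyze a batch of eye images
#'
#' Runs load -> detect -> score -> aggregate over each path. Images are
#' processed concurrently up to `workers` (forked processes) and the rows are
#' reassembled in input order, so the result is identical for any worker
#' count. A failure on one image yields an error record for that row and does
#' not abort the batch; per-image analyses share no state, so batch results
#' equal single-image runs.
#'
#' @param paths Character vector of image files (at least one).
#' @param horizontal Images were acquired horizontally (rotated to vertical on
#'   load).
#' @param sem Use SEM preprocessing instead of bright-field.
#' @param n Count of most-ordered stable ommatidia per image (default 200).
#' @param workers Number of parallel workers (>= 1).
#' @param csv Optional path; when set the result table is exported with
#'   [write_results_csv()].
#' @param params [detection_params()] shared by all images.
#' @param quiet Suppress the one-line-per-image progress messages.
#' @return A tibble (class `ommatidia_results`) with one row per input path in
#'   input order: `file`, `ODI_D`, `ODI_A`, `ODI`, `Z`, `P`, `N_used`,
#'   `error` (`NA` on success).
#' @export
run_batch <- function(paths, horizontal = FALSE, sem = FALSE, n = 200,
                      workers = 1, csv = NULL, params = detection_params(),
                      quiet = TRUE) {
  if (length(paths) < 1) {
    stop_ommatidia("at least one image path is required", class = "validation",
                   field = "paths")
  }
  check_number(n, "n", min = 1, integer = TRUE)
  check_number(workers, "workers", min = 1, integer = TRUE)
  modality <- if (isTRUE(sem)) "sem" else "brightfield"

  one <- function(path) {
    t0 <- proc.time()[["elapsed"]]
    analyze_quietly <- function() {
      img <- load_image(path, modality = modality, horizontal = horizontal)
      fit <- if (quiet) {
        suppressMessages(analyze_eye(img, params = params, n = n))
      } else {
        analyze_eye(img, params = params, n = n)
      }
      res <- glance(fit)
      res$error <- NA_character_
      res
    }
    row <- tryCatch(analyze_quietly(), error = function(e) {
      result_error_row(basename(path), conditionMessage(e))
    })
    if (!quiet) {
      inform(sprintf("%s: Z = %s, P = %s (%.2f s)",
                     row$file,
                     ifelse(is.na(row$Z), "NA", row$Z),
                     ifelse(is.na(row$P), "NA", sprintf("%.4f", row$P)),
                     proc.time()[["elapsed"]] - t0))
    }
    row
  }

  rows <- if (workers > 1 && .Platform$OS.type == "unix") {
    parallel::mclapply(paths, one, mc.cores = workers)
  } else {
    lapply(paths, one)
  }
  table <- dplyr::bind_rows(rows)
  class(table) <- c("ommatidia_results", class(table))
  if (!is.null(csv)) write_results_csv(table, csv)
  table
}

format_result_line <- function(row) {
  if (is.na(row$Z)) {
    sprintf("%s,NA,NA,NA,NA,NA", row$file)
  } else {
    sprintf("%s,%.4f,%.4f,%.4f,%d,%.4f",
            row$file, row$ODI_D, row$ODI_A, row$ODI, row$Z, row$P)
  }
}

#' Export a result table to CSV
#'
#' Writes the header `file,ODI_D,ODI_A,ODI,Z,P` followed by one row per image
#' in input order; floating-point values with 4 decimal places, Z as an
#' integer, and `NA` in all five value fields for error rows. The fixed
#' formatting makes repeated runs byte-identical.
#'
#' @param table A result table from [run_batch()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_results_csv <- function(table, path) {
  lines <- c("file,ODI_D,ODI_A,ODI,Z,P",
             vapply(seq_len(nrow(table)),
                    function(i) format_result_line(table[i, ]),
                    character(1)))
  tryCatch(writeLines(lines, path),
           error = function(e) {
             stop_ommatidia(paste0("cannot write CSV: ", path), class = "io",
                            path = path, parent = e)
           })
  invisible(path)
}
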