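fmt2 <- function(x) formatC(x, format = "f", digits = 2)

#' Write analysis results to disk
#'
#' Serialises whichever results are supplied to a deterministic set of
#' files under `out_dir`: an evaluation summary (`evaluation.csv` with
#' two-decimal euros plus `evaluation.json` at full precision and with
#' the whole-euro headline figures), the ranked tornado table
#' (`tornado.csv`), the PSA draws (`psa_draws.csv`) and summary
#' (`psa_summary.json`), and the remuneration composition
#' (`remuneration.csv`, two columns: label, EUR). Column order is fixed
#' and numbers are serialised with explicit precision, so identical
#' inputs produce byte-identical files.
#'
#' @param results Named list with any of `evaluation` (an
#'   `evaluation_result`), `tornado` (a `tornado_result`), `psa` (a
#'   `psa_result`), `remuneration` (a `remuneration`).
#' @param out_dir Output directory; created if missing.
#' @return Character vector of the files written, invisibly.
#' @export
write_report <- function(results, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(out_dir)) {
      stop(sprintf("cannot create output directory '%s'", out_dir),
           call. = FALSE)
    }
  }
  written <- character()
  add <- function(f) written <<- c(written, f)

  ev <- results$evaluation
  if (!is.null(ev)) {
    f <- file.path(out_dir, "evaluation.csv")
    df <- data.frame(
      perspective = ev$perspective,
      alternative = names(ev$expected_cost),
      expected_cost_eur = fmt2(unname(ev$expected_cost)),
      rounded_eur = round(unname(ev$expected_cost)),
      stringsAsFactors = FALSE
    )
    utils::write.csv(df, f, row.names = FALSE, quote = TRUE)
    add(f)
    j <- file.path(out_dir, "evaluation.json")
    jsonlite::write_json(list(
      perspective = ev$perspective,
      expected_cost = as.list(ev$expected_cost),
      incremental = ev$incremental,
      rounded = list(
        expected_cost = as.list(round(ev$expected_cost)),
        saving = round(ev$expected_cost[["usual_practice"]]) -
          round(ev$expected_cost[["intervention"]])
      )
    ), j, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    add(j)
  }

  tr <- results$tornado
  if (!is.null(tr)) {
    f <- file.path(out_dir, "tornado.csv")
    df <- data.frame(
      parameter = tr$parameter, low = fmt2(tr$low), high = fmt2(tr$high),
      incremental_low = fmt2(tr$incremental_at_low),
      incremental_high = fmt2(tr$incremental_at_high),
      swing = fmt2(tr$swing), stringsAsFactors = FALSE
    )
    utils::write.csv(df, f, row.names = FALSE, quote = TRUE)
    add(f)
  }

  psa <- results$psa
  if (!is.null(psa)) {
    f <- file.path(out_dir, "psa_draws.csv")
    df <- data.frame(draw = seq_along(psa$draws),
                     incremental_eur = fmt2(psa$draws))
    utils::write.csv(df, f, row.names = FALSE, quote = TRUE)
    add(f)
    j <- file.path(out_dir, "psa_summary.json")
    jsonlite::write_json(list(
      mean = psa$mean, sd = psa$sd, q025 = psa$q025, q975 = psa$q975,
      fraction_cost_saving = psa$fraction_cost_saving,
      n_draws = psa$n_draws, seed = psa$seed,
      excluded_ids = as.list(psa$excluded_ids)
    ), j, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    add(j)
  }

  rem <- results$remuneration
  if (!is.null(rem)) {
    f <- file.path(out_dir, "remuneration.csv")
    df <- data.frame(label = c(rem$components$label, "Total"),
                     eur = fmt2(c(rem$components$cost, rem$total)),
                     stringsAsFactors = FALSE)
    utils::write.csv(df, f, row.names = FALSE, quote = TRUE)
    add(f)
  }

  invisible(written)
}
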