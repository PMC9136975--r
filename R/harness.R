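#' End-to-end bit-error-ratio benchmark
#'
#' Builds a seeded unit-patch library, generates disjoint training and
#' evaluation sets, trains the CNN decoder, and evaluates its bit error
#' ratio. The reference recipe uses 9,494 training and 50,000 validation
#' images of 7 x 7 codes at 648 x 692 resolution; the desk profile runs
#' the same pipeline at 96 x 96.
#'
#' @param train_n,eval_n set sizes (single-channel labelled images).
#' @param imaging an `imaging_config`.
#' @param cnn a `cnn_config` matching the imaging canvas.
#' @param n_patches unit-patch pool size per class (filled/empty).
#' @param seed master seed; library, training and evaluation sets derive
#'   distinct sub-seeds from it.
#' @param out_dir optional directory for JSON + CSV reports.
#' @param verbose print training progress.
#' @return List with the trained `decoder`, the `ber_report`, and the
#'   baseline report on the same evaluation set.
#' @export
run_ber_benchmark <- function(train_n, eval_n,
                              imaging = imaging_config("desk"),
                              cnn = cnn_config("desk", n = imaging$n),
                              n_patches = 200L, seed = 1L,
                              out_dir = NULL, verbose = FALSE) {
  stopifnot(train_n >= 1, eval_n >= 1)
  if (!all(cnn$input_shape == imaging$canvas))
    stop("cnn input_shape must equal the imaging canvas")
  seeds <- derive_seeds(seed, 3L)
  library <- build_patch_library(n_patches, imaging, seed = seeds[1])
  library <- resize_patch_library(library, imaging$unit_active_side)
  train_set <- generate_dataset(train_n, library, imaging, seed = seeds[2])
  eval_set <- generate_dataset(eval_n, library, imaging, seed = seeds[3])
  cnn$seed <- seeds[1]
  model <- build_decoder(cnn)
  model <- train_decoder(model, train_set, verbose = verbose)
  report <- evaluate_ber(model, eval_set)
  layout <- grid_layout(imaging)
  baseline_report <- evaluate_ber(layout, eval_set)
  result <- list(decoder = model, report = report,
                 baseline_report = baseline_report,
                 provenance = list(seed = seed, train_n = train_n,
                                   eval_n = eval_n,
                                   config_hash = config_hash(imaging)))
  if (!is.null(out_dir)) write_ber_report(result, out_dir)
  result
}

# distinct 31-bit sub-seeds from one master seed
derive_seeds <- function(seed, k) {
  set.seed(seed)
  sample.int(.Machine$integer.max, k)
}

write_ber_report <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rp <- result$report
  jsonlite::write_json(
    list(ber = rp$ber, n_images = rp$n_images, n_bits_total = rp$n_bits_total,
         n_bit_errors = rp$n_bit_errors, decoder = rp$decoder,
         baseline_ber = result$baseline_report$ber,
         provenance = result$provenance),
    file.path(out_dir, "ber_report.json"), auto_unbox = TRUE, digits = NA)
  pc <- as.data.frame(rp$per_channel)
  pc$channel <- rownames(rp$per_channel)
  utils::write.csv(pc[, c("channel", "bits", "errors", "ber")],
                   file.path(out_dir, "ber_per_channel.csv"),
                   row.names = FALSE)
  invisible(out_dir)
}

#' Bit-error response to fluorescence intensity degradation
#'
#' Re-renders evaluation images at decreasing remaining-intensity
#' fractions (emulating photobleaching or thermal loss) with paired
#' seeds — the same codes, patch draws and noise at every fraction — and
#' measures the fixed decoder's BER at each level. Mirrors the
#' observation that bit errors stay negligible while fluorescence
#' intensity is maintained above ~75%.
#'
#' @param decoder trained `cnn_decoder` or `grid_layout`.
#' @param fractions intensity fractions in [0,1]; sorted descending.
#' @param n_images evaluation images per fraction.
#' @param library a `patch_library` (at the composing side).
#' @param imaging an `imaging_config`.
#' @param seed seed reused for every fraction (paired comparison).
#' @return A `sweep_report`: data frame of per-fraction BER plus a
#'   monotonicity flag (BER non-increasing in fraction).
#' @export
run_degradation_sweep <- function(decoder, fractions = c(1.0, 0.9, 0.75, 0.5, 0.25),
                                  n_images = 100L,
                                  library, imaging = imaging_config("desk"),
                                  seed = 1L) {
  if (length(fractions) == 0) stop("empty fraction list")
  if (any(fractions < 0 | fractions > 1)) stop("fractions must lie in [0,1]")
  fractions <- sort(fractions, decreasing = TRUE)
  bers <- vapply(fractions, function(f) {
    cfg <- imaging
    cfg$intensity_fraction <- f
    es <- generate_dataset(n_images, library, cfg, seed = seed)
    evaluate_ber(decoder, es, strict = FALSE)$ber
  }, 0)
  df <- data.frame(intensity_fraction = fractions, ber = bers)
  structure(list(results = df,
                 monotone = !is.unsorted(bers),  # BER grows as fraction falls
                 decoder = if (inherits(decoder, "cnn_decoder")) "cnn"
                           else "baseline",
                 provenance = list(seed = seed, n_images = n_images,
                                   config_hash = config_hash(imaging))),
            class = "sweep_report")
}

#' @export
print.sweep_report <- function(x, ...) {
  cat("degradation sweep (", x$decoder, " decoder, ",
      x$provenance$n_images, " images/fraction)\n", sep = "")
  print(x$results, row.names = FALSE)
  cat(if (x$monotone) "BER is monotone non-increasing in intensity fraction\n"
      else "BER is NOT monotone in intensity fraction\n")
  invisible(x)
}

#' Hemolysis efficiency from absorbance readings
#'
#' `(A_S - A_N) / (A_P - A_N) * 100` (%), where `A_S`, `A_P` and `A_N`
#' are optical absorbances at 580 nm of the sample, the positive control
#' (0.1% Triton X-100, 100% lysis) and the negative control (PBS, 0%).
#' Values outside [0, 100] are returned unclamped with an
#' `out_of_range` attribute.
#'
#' @param A_S sample absorbance(s); vectorized.
#' @param A_P positive-control absorbance.
#' @param A_N negative-control absorbance.
#' @return Hemolysis efficiency in percent.
#' @export
hemolysis_efficiency <- function(A_S, A_P, A_N) {
  if (isTRUE(all.equal(A_P, A_N)))
    stop("degenerate controls: A_P must differ from A_N")
  eff <- (A_S - A_N) / (A_P - A_N) * 100
  attr(eff, "out_of_range") <- eff < 0 | eff > 100
  eff
}
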