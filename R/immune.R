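#' Immune-optimizer configuration
#'
#' Parameters of the clonal-selection search over the joint space of SVM
#' hyperparameters and feature masks. The defaults follow the study
#' protocol: 5 initial antibody groups, a 10x replication rate for
#' general antibodies and 30x for the best one per cycle, and a cap of
#' 500 cycles.
#'
#' @param n_groups number of antibodies in the population (default 5).
#' @param bits_per_field bits n per encoded field; an antibody is
#'   32 * n bits: 2 parameter fields (C, r) plus 30 feature-screen
#'   fields (default 8).
#' @param clone_general clones per ordinary antibody per cycle
#'   (default 10).
#' @param clone_best clones of the best-affinity antibody (default 30,
#'   must exceed `clone_general`).
#' @param max_generations cycle cap (default 500).
#' @param target_affinity stop early once best affinity reaches this
#'   (default 1, i.e. run to the cycle cap unless perfect).
#' @param mutation_rate per-bit flip probability for clones; default
#'   `1 / bits_per_field`, so longer field encodings mutate each bit
#'   more rarely.
#' @param c_bounds,r_bounds decoded bounds for the SVM cost C and RBF
#'   kernel width r, decoded on a log2 scale over the standard search
#'   box C in \[2^-5, 2^15\], r in \[2^-15, 2^3\].
#' @param seed integer seed making the whole run reproducible.
#' @return a list of class `ia_config`.
#' @export
ia_config <- function(n_groups = 5L, bits_per_field = 8L,
                      clone_general = 10L, clone_best = 30L,
                      max_generations = 500L, target_affinity = 1.0,
                      mutation_rate = NULL,
                      c_bounds = c(2^-5, 2^15), r_bounds = c(2^-15, 2^3),
                      seed = 1L) {
  cfg <- list(n_groups = as.integer(n_groups),
              bits_per_field = as.integer(bits_per_field),
              clone_general = as.integer(clone_general),
              clone_best = as.integer(clone_best),
              max_generations = as.integer(max_generations),
              target_affinity = target_affinity,
              mutation_rate = if (is.null(mutation_rate))
                1 / as.integer(bits_per_field) else mutation_rate,
              c_bounds = c_bounds, r_bounds = r_bounds,
              seed = as.integer(seed))
  if (cfg$n_groups < 2L) stop("`n_groups` must be >= 2")
  if (cfg$bits_per_field < 1L) stop("`bits_per_field` must be >= 1")
  if (cfg$clone_general < 1L || cfg$clone_best <= cfg$clone_general)
    stop("need clone_best > clone_general >= 1")
  if (cfg$target_affinity > 1) stop("`target_affinity` must be <= 1")
  if (any(c_bounds[2] <= c_bounds[1], r_bounds[2] <= r_bounds[1]))
    stop("parameter bounds must satisfy upper > lower")
  class(cfg) <- "ia_config"
  cfg
}

N_FEATURES <- 30L
N_FIELDS <- 32L   # C, r, then 30 feature screens

#' Decode a binary field to a real parameter
#'
#' Maps an l-bit field to the uniform grid of 2^l values on
#' \[lower, upper\]: x = d + (u - d) / (2^l - 1) * sum_j a_j 2^(j-1),
#' with bit 1 the least significant. All-zero bits decode to the lower
#' bound, all-one bits to the upper bound, and the map is strictly
#' increasing in the field's integer value.
#'
#' @param bits integer/logical vector of 0/1, length >= 1.
#' @param lower,upper decoded bounds, `upper > lower`.
#' @return decoded value in \[lower, upper\].
#' @export
decode_field <- function(bits, lower, upper) {
  if (upper <= lower) stop("`upper` must exceed `lower`")
  l <- length(bits)
  if (l < 1L || !all(bits %in% c(0, 1))) stop("`bits` must be 0/1, length >= 1")
  v <- sum(bits * 2^(seq_len(l) - 1))
  lower + (upper - lower) / (2^l - 1) * v
}

#' Encode a grid value back to a binary field
#'
#' Inverse of [decode_field()] on the decoding grid: returns the l-bit
#' pattern whose decoded value is nearest to `x`.
#'
#' @param x value in \[lower, upper\].
#' @param l field length in bits.
#' @inheritParams decode_field
#' @return integer 0/1 vector of length `l`.
#' @export
encode_field <- function(x, l, lower, upper) {
  v <- round((x - lower) / (upper - lower) * (2^l - 1))
  v <- min(max(v, 0), 2^l - 1)
  as.integer(intToBits(v)[seq_len(l)])
}

#' Decode an antibody chromosome
#'
#' Splits the 32 * n bit string into 32 consecutive n-bit fields: field 1
#' decodes (log2 scale) to the SVM cost C, field 2 to the RBF width r,
#' and fields 3..32 are feature screens — feature k is selected when its
#' field decodes to at least the midpoint of \[0, 1\].
#'
#' @param bits 0/1 vector of length `32 * cfg$bits_per_field`.
#' @param cfg an [ia_config()].
#' @return list with `C`, `r`, `mask` (30 logicals).
#' @export
decode_antibody <- function(bits, cfg) {
  n <- cfg$bits_per_field
  if (length(bits) != N_FIELDS * n) stop("antibody has wrong bit length")
  fld <- function(k) bits[((k - 1L) * n + 1L):(k * n)]
  C <- 2^decode_field(fld(1L), log2(cfg$c_bounds[1]), log2(cfg$c_bounds[2]))
  r <- 2^decode_field(fld(2L), log2(cfg$r_bounds[1]), log2(cfg$r_bounds[2]))
  mask <- vapply(seq_len(N_FEATURES),
                 function(k) decode_field(fld(k + 2L), 0, 1) >= 0.5,
                 logical(1))
  list(C = C, r = r, mask = mask)
}

# ensure at least one feature is screened in: flip one random feature
# field to all ones
.repair_antibody <- function(bits, cfg) {
  n <- cfg$bits_per_field
  mask <- decode_antibody(bits, cfg)$mask
  if (!any(mask)) {
    k <- sample.int(N_FEATURES, 1L)
    bits[((k + 1L) * n + 1L):((k + 2L) * n)] <- 1L
  }
  bits
}

new_antibody <- function(bits, lineage) {
  list(bits = as.integer(bits), lineage = as.integer(lineage),
       affinity = NA_real_)
}

#' Initialize an antibody population
#'
#' Draws `cfg$n_groups` antibodies with independent fair-coin bits
#' (repaired so every antibody screens in at least one feature). Uses
#' the current RNG state; [run_optimization()] seeds it from the config.
#'
#' @param cfg an [ia_config()].
#' @return list of antibodies (each a list with `bits`, `lineage`,
#'   `affinity`).
#' @export
init_population <- function(cfg) {
  len <- N_FIELDS * cfg$bits_per_field
  lapply(seq_len(cfg$n_groups), function(i) {
    bits <- .repair_antibody(sample(0:1, len, replace = TRUE), cfg)
    new_antibody(bits, i)
  })
}

#' Cross-validated SVM affinity of an antibody
#'
#' The affinity between an antibody and the recognition problem is the
#' mean 5-fold cross-validated accuracy of an RBF-SVM with the decoded
#' (C, r) trained on the screened feature columns, using the dataset's
#' stored fold assignment. Standardization statistics come from the
#' training folds only.
#'
#' @param ab an antibody.
#' @param data a [labeled_dataset()].
#' @param cfg an [ia_config()].
#' @return accuracy in \[0, 1\].
#' @export
svm_affinity <- function(ab, data, cfg) {
  ph <- decode_antibody(ab$bits, cfg)
  if (!any(ph$mask)) stop("internal error: empty feature mask")
  spec <- svm_model_spec(cost = ph$C, gamma = ph$r)
  cv_accuracy(data, spec, columns = which(ph$mask))$overall
}

#' Clone and mutate a population
#'
#' Clonal expansion step: the single best-affinity antibody contributes
#' `clone_best` copies and every other antibody `clone_general` copies;
#' each clone is hypermutated by independent per-bit flips at
#' `cfg$mutation_rate` and repaired. Parents are returned untouched by
#' the caller; only clones mutate.
#'
#' @param pop list of antibodies, all with affinity set.
#' @param cfg an [ia_config()].
#' @return list of mutated clones carrying their parent's lineage.
#' @export
clone_and_mutate <- function(pop, cfg) {
  aff <- vapply(pop, function(a) a$affinity, 0)
  if (anyNA(aff)) stop("all antibodies must be evaluated before cloning")
  best <- which.max(aff)
  len <- length(pop[[1]]$bits)
  clones <- list()
  for (i in seq_along(pop)) {
    n_cl <- if (i == best) cfg$clone_best else cfg$clone_general
    for (k in seq_len(n_cl)) {
      bits <- pop[[i]]$bits
      flip <- stats::runif(len) < cfg$mutation_rate
      bits[flip] <- 1L - bits[flip]
      clones[[length(clones) + 1L]] <-
        new_antibody(.repair_antibody(bits, cfg), pop[[i]]$lineage)
    }
  }
  clones
}

#' Elitist per-lineage selection
#'
#' For each parent lineage, the best of \{parent, its clones\} survives,
#' so the population size returns to `n_groups` and the best affinity
#' never decreases.
#'
#' @param parents,clones evaluated antibody lists.
#' @param cfg an [ia_config()].
#' @return list of `cfg$n_groups` antibodies.
#' @export
select_next_generation <- function(parents, clones, cfg) {
  out <- vector("list", length(parents))
  for (i in seq_along(parents)) {
    lin <- parents[[i]]$lineage
    cand <- c(list(parents[[i]]),
              Filter(function(a) a$lineage == lin, clones))
    aff <- vapply(cand, function(a) a$affinity, 0)
    out[[i]] <- cand[[which.max(aff)]]
  }
  out
}

#' Run the optimized immune algorithm
#'
#' Full clonal-selection loop: initialize, evaluate, clone and
#' hypermutate, then retain the best of each lineage, repeating until the
#' best affinity reaches `cfg$target_affinity` or `cfg$max_generations`
#' cycles have run. By default affinity is the cross-validated RBF-SVM
#' accuracy on the screened features ([svm_affinity()]); `affinity_fun`
#' substitutes any objective mapping an antibody to \[0, 1\] (used for
#' surrogate-landscape calibration).
#'
#' @param data a [labeled_dataset()] (may be `NULL` when `affinity_fun`
#'   ignores it).
#' @param cfg an [ia_config()].
#' @param affinity_fun function(ab, data, cfg) -> affinity in \[0, 1\];
#'   default [svm_affinity()].
#' @return list of class `ia_result`: `best` (antibody), `phenotype`
#'   (decoded C, r, mask), `history` (data.frame with generation,
#'   best_affinity, mean_affinity, objective = 1 - best_affinity),
#'   `evaluations` (number of affinity evaluations, i.e. SVM
#'   cross-validation runs).
#' @export
run_optimization <- function(data, cfg, affinity_fun = svm_affinity) {
  if (!inherits(cfg, "ia_config")) stop("`cfg` must be an ia_config")
  if (!is.null(data) && nlevels(data$labels) < 2)
    stop("dataset must contain at least two classes")
  set.seed(cfg$seed)
  evals <- 0L
  evaluate <- function(pop) {
    lapply(pop, function(a) {
      if (is.na(a$affinity)) {
        a$affinity <- affinity_fun(a, data, cfg)
        evals <<- evals + 1L
      }
      a
    })
  }
  pop <- evaluate(init_population(cfg))
  hist_rows <- vector("list", cfg$max_generations)
  gen <- 0L
  repeat {
    gen <- gen + 1L
    aff <- vapply(pop, function(a) a$affinity, 0)
    hist_rows[[gen]] <- data.frame(
      generation = gen, best_affinity = max(aff), mean_affinity = mean(aff),
      objective = 1 - max(aff))
    if (max(aff) >= cfg$target_affinity || gen >= cfg$max_generations) break
    clones <- evaluate(clone_and_mutate(pop, cfg))
    pop <- select_next_generation(pop, clones, cfg)
  }
  aff <- vapply(pop, function(a) a$affinity, 0)
  best <- pop[[which.max(aff)]]
  structure(list(best = best,
                 phenotype = decode_antibody(best$bits, cfg),
                 history = do.call(rbind, hist_rows[seq_len(gen)]),
                 evaluations = evals,
                 config = cfg),
            class = "ia_result")
}

#' @export
print.ia_result <- function(x, ...) {
  ph <- x$phenotype
  cat(sprintf(paste0("optimized immune algorithm: best affinity %.4f ",
                     "after %d generations (%d evaluations)\n"),
              x$best$affinity, nrow(x$history), x$evaluations))
  cat(sprintf("  C = %.4g, r = %.4g, %d/%d features selected\n",
              ph$C, ph$r, sum(ph$mask), length(ph$mask)))
  invisible(x)
}

#' Write a convergence history and plot
#'
#' Exports the per-generation history as CSV and, optionally, a PNG of
#' the objective (1 - best affinity) against the cycle number — the
#' curve drops fast over the first cycles, then flattens as the search
#' turns local.
#'
#' @param result an `ia_result` from [run_optimization()].
#' @param csv_path output CSV path (generation, best_affinity,
#'   mean_affinity, objective).
#' @param png_path optional output plot path.
#' @return `csv_path`, invisibly.
#' @export
export_history <- function(result, csv_path, png_path = NULL) {
  utils::write.csv(result$history, csv_path, row.names = FALSE)
  if (!is.null(png_path)) {
    grDevices::png(png_path, width = 720, height = 480)
    on.exit(grDevices::dev.off())
    graphics::plot(result$history$generation, result$history$objective,
                   type = "l", xlab = "cycle", ylab = "1 - best affinity",
                   main = "Immune optimization convergence")
  }
  invisible(csv_path)
}
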