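# Ground-truthed synthetic data: peptide sets, MS1 runs, and complete
# titration experiments emulating the 16O/18O blocking-and-titration assay.

#' Generate a synthetic tryptic-like peptide set
#'
#' Sequences of length 8-25 ending in K/R, by default with exactly one
#' methionine (the labeled site) and no cysteine (excluded from the assay).
#' Deterministic for a fixed seed.
#'
#' @param n Number of peptides.
#' @param seed Integer seed.
#' @param require_single_met Force exactly one M per sequence.
#' @param exclude_cys Exclude C from the alphabet.
#' @return Character vector of `n` unique sequences.
#' @export
generate_peptide_set <- function(n, seed = 1L, require_single_met = TRUE,
                                 exclude_cys = TRUE) {
  if (n < 1L) stop("n must be at least 1")
  set.seed(seed)
  alphabet <- setdiff(rownames(.AA_COMPOSITIONS), c("K", "R", "M"))
  if (exclude_cys) alphabet <- setdiff(alphabet, "C")
  if (!require_single_met) alphabet <- c(alphabet, "M")
  out <- character(0)
  while (length(out) < n) {
    len <- sample(8:25, 1L)
    body <- sample(alphabet, len - 1L, replace = TRUE)
    if (require_single_met)
      body[sample(seq_len(len - 2L), 1L)] <- "M"   # interior position
    seq <- paste0(paste(body, collapse = ""), sample(c("K", "R"), 1L))
    if (require_single_met && sum(strsplit(seq, "")[[1]] == "M") != 1L) next
    if (!seq %in% out) out <- c(out, seq)
  }
  out
}

# default in vivo MOS distribution: mostly low stoichiometries (median near
# 0.045) with a 10% oxidation-prone upper tail
.default_mos_draw <- function(n) {
  n_tail <- round(0.1 * n)
  base <- stats::rbeta(n - n_tail, 2.5, 50)
  tail <- stats::runif(n_tail, 0.2, 0.6)
  sample(c(base, tail))
}

#' Build the ground truth of a synthetic titration experiment
#'
#' @param n_peptides Number of labeled peptides.
#' @param design Run design ([make_titration_design()]).
#' @param mos_true Optional vector of true in vivo MOS values (recycled);
#'   defaults to a draw with median near 0.045 and a 10% upper tail.
#' @param seed Integer seed.
#' @param noise_sdlog Lognormal multiplicative peak noise (sdlog).
#' @param noise_add_sd Additive Gaussian peak noise (intensity units).
#' @param purity Heavy-labeling reagent isotopic purity in (0, 1\];
#'   `1 - purity` of the blocked sulfoxides carry a 16O oxygen.
#' @param rt_window Run retention-time window, minutes.
#' @param scan_interval Scan cycle time, seconds.
#' @param charges Charge states sampled per peptide.
#' @param K Isotopologues simulated per species.
#' @return A `mos_truth` list: `peptides`, `runs`, `params`.
#' @export
simulation_truth <- function(n_peptides = 50L,
                             design = make_titration_design(),
                             mos_true = NULL, seed = 1L,
                             noise_sdlog = 0.01, noise_add_sd = 0,
                             purity = 1.0,
                             rt_window = c(0, 2), scan_interval = 1.0,
                             charges = 2:3, K = 6L) {
  if (purity <= 0 || purity > 1) stop("purity must be in (0, 1]")
  set.seed(seed)
  sequences <- generate_peptide_set(n_peptides, seed = seed)
  if (is.null(mos_true)) mos_true <- .default_mos_draw(n_peptides)
  mos_true <- rep_len(mos_true, n_peptides)
  span <- diff(rt_window)
  peptides <- data.frame(
    peptide = sequences,
    sequence = sequences,
    charge = sample(charges, n_peptides, replace = TRUE),
    mos_true = mos_true,
    rt_mu = stats::runif(n_peptides, rt_window[1] + 0.15 * span,
                         rt_window[2] - 0.15 * span),
    rt_sigma = 0.05,
    abundance = stats::rlnorm(n_peptides, log(1e6), 0.4),
    stringsAsFactors = FALSE)
  runs <- design
  runs$purity <- purity
  runs$noise_sdlog <- noise_sdlog
  runs$noise_add_sd <- noise_add_sd
  runs$run_seed <- (seed + 7919L * seq_len(nrow(design))) %% .Machine$integer.max
  structure(list(peptides = peptides, runs = runs,
                 params = list(seed = seed, rt_window = rt_window,
                               scan_interval = scan_interval, K = K,
                               merge_tol_mz = 0.004)),
            class = "mos_truth")
}

#' Simulate one MS1 run of a titration experiment
#'
#' Places the light and heavy species of every peptide at their theoretical
#' isotopologue m/z with Gaussian elution in retention time. The light
#' fraction of each peptide is the carrier-mixing value
#' `f = t + (1 - t) * MOS_true`; reagent impurity moves `1 - purity` of the
#' heavy species' signal to the light positions. Peaks closer than the
#' resolution-limited merge tolerance (heavy isotopologue k vs light k+2,
#' 0.0025 Da apart per charge) are merged into one centroid, which is what
#' creates the envelope overlap the correction must undo. Multiplicative
#' lognormal and additive Gaussian noise are applied per peak.
#'
#' @param truth A `mos_truth` from [simulation_truth()].
#' @param run_id A run name present in `truth$runs$run`.
#' @return List: `ms1` (an [ms1_map()]) and `evidence` (one row per species:
#'   sequence, modifications token, charge, mz, rt, raw_file, score).
#' @export
simulate_ms1_run <- function(truth, run_id) {
  stopifnot(inherits(truth, "mos_truth"))
  run <- truth$runs[truth$runs$run == run_id, ]
  if (nrow(run) != 1L) stop("unknown run: ", run_id)
  p <- truth$params
  set.seed(run$run_seed)
  rt <- seq(p$rt_window[1], p$rt_window[2], by = p$scan_interval / 60)

  pep <- truth$peptides
  n_pep <- nrow(pep)
  mz_list <- vector("list", n_pep)
  base_list <- vector("list", n_pep)
  ev_rows <- vector("list", n_pep)
  for (i in seq_len(n_pep)) {
    comp <- composition_from_sequence(pep$sequence[i], "mso16")
    env <- isotope_envelope(comp, K = p$K)
    geom <- pair_positions(env, pep$charge[i])
    f <- run$t + (1 - run$t) * pep$mos_true[i]
    light_tot <- pep$abundance[i] * (f + (1 - f) * (1 - run$purity))
    heavy_tot <- pep$abundance[i] * (1 - f) * run$purity
    mz_list[[i]] <- c(geom$light_mz, geom$heavy_mz)
    base_list[[i]] <- c(light_tot * env$abundances, heavy_tot * env$abundances)
    ev_rows[[i]] <- data.frame(
      sequence = rep(pep$sequence[i], 2),
      modifications = c("mso16", "mso18"),
      charge = rep(pep$charge[i], 2),
      mz = c(geom$light_mz[1], geom$heavy_mz[1]),
      rt = rep(pep$rt_mu[i], 2),
      raw_file = rep(run_id, 2),
      score = rep(pep$abundance[i], 2),
      stringsAsFactors = FALSE)
  }
  all_mz <- unlist(mz_list)
  all_base <- unlist(base_list)
  pep_of_peak <- rep(seq_len(n_pep), vapply(mz_list, length, 0L))

  peaks <- vector("list", length(rt))
  for (s in seq_along(rt)) {
    g <- exp(-(rt[s] - pep$rt_mu)^2 / (2 * pep$rt_sigma^2))
    g[abs(rt[s] - pep$rt_mu) > 4 * pep$rt_sigma] <- 0
    ints <- all_base * g[pep_of_peak]
    live <- ints > 0
    mzs <- all_mz[live]; ints <- ints[live]
    if (length(ints) > 0L) {
      if (run$noise_sdlog > 0)
        ints <- ints * exp(stats::rnorm(length(ints), 0, run$noise_sdlog))
      if (run$noise_add_sd > 0)
        ints <- pmax(0, ints + stats::rnorm(length(ints), 0, run$noise_add_sd))
      ord <- order(mzs)
      mzs <- mzs[ord]; ints <- ints[ord]
      grp <- cumsum(c(1L, diff(mzs) > p$merge_tol_mz))
      merged_int <- rowsum(ints, grp)[, 1]
      merged_mz <- rowsum(mzs * ints, grp)[, 1] / pmax(merged_int, 1e-300)
      zero <- merged_int <= 0
      if (any(zero)) merged_mz[zero] <- rowsum(mzs, grp)[zero, 1] /
          tabulate(grp)[zero]
      keep <- merged_int > 0
      peaks[[s]] <- cbind(mz = merged_mz[keep], intensity = merged_int[keep])
    } else {
      peaks[[s]] <- cbind(mz = numeric(0), intensity = numeric(0))
    }
  }
  list(ms1 = ms1_map(rt, peaks, run_id = run_id),
       evidence = do.call(rbind, ev_rows))
}

#' Simulate a complete titration experiment
#'
#' Generates every run of the design plus the matching evidence, design and
#' ground-truth tables. With `write_dir` set, runs are written as mzML and
#' the tables as TSV, with all generation parameters echoed to a JSON
#' sidecar; otherwise everything stays in memory.
#'
#' @inheritParams simulation_truth
#' @param truth Optionally a prebuilt `mos_truth` (overrides the other
#'   generation arguments).
#' @param write_dir Optional output directory.
#' @param ... Passed to [simulation_truth()].
#' @return List: `truth`, `design`, `evidence` (all runs), `runs` (named
#'   list of [ms1_map()]), and `paths` when written to disk.
#' @export
simulate_experiment <- function(n_peptides = 50L,
                                design = make_titration_design(),
                                seed = 1L, truth = NULL, write_dir = NULL,
                                ...) {
  if (is.null(truth))
    truth <- simulation_truth(n_peptides = n_peptides, design = design,
                              seed = seed, ...)
  run_ids <- truth$runs$run
  maps <- vector("list", length(run_ids))
  ev <- vector("list", length(run_ids))
  for (i in seq_along(run_ids)) {
    sim <- simulate_ms1_run(truth, run_ids[i])
    maps[[i]] <- sim$ms1
    ev[[i]] <- sim$evidence
  }
  names(maps) <- run_ids
  evidence <- do.call(rbind, ev)
  out <- list(truth = truth, design = truth$runs, evidence = evidence,
              runs = maps)
  if (!is.null(write_dir)) {
    dir.create(write_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- character(0)
    for (id in run_ids) {
      f <- file.path(write_dir, paste0(id, ".mzML"))
      write_ms1(maps[[id]], f)
      paths <- c(paths, f)
    }
    utils::write.table(evidence, file.path(write_dir, "evidence.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(truth$runs, file.path(write_dir, "design.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(truth$peptides, file.path(write_dir, "truth.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    jsonlite::write_json(truth$params,
                         file.path(write_dir, "simulation_params.json"),
                         auto_unbox = TRUE, digits = NA)
    out$paths <- paths
  }
  out
}
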