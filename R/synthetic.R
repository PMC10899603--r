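## Seeded generators producing fixtures with the statistical structure each
## pipeline stage assumes. Every generator takes a single integer seed, never
## touches global RNG state (see with_seed), and can serialize its output
## with a JSON ground-truth sidecar.

write_truth_sidecar <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Generate a homolog alignment with planted consensus signals
#'
#' Builds a random reference protein and `n_homologs` homologs mutated to hit
#' target identities drawn from `identity_range`. At each planted position
#' the consensus residue is assigned to `ceiling(majority_fraction *
#' n_homologs)` homologs and the remaining homologs receive residues distinct
#' from both wildtype and consensus, so planted signals satisfy the default
#' calling thresholds with margin.
#'
#' @param seed integer seed.
#' @param n_homologs number of homologs (default 18).
#' @param ref_length reference length in residues (default 460).
#' @param identity_range target identity range (default c(0.62, 0.95)).
#' @param planted_calls `NULL` or data frame `position`, `wt`, `consensus`.
#' @param majority_fraction homolog fraction carrying the consensus residue
#'   at planted positions (default 0.6).
#' @param out_dir optional directory: writes `msa.fasta` plus
#'   `msa_truth.json`.
#' @return List `alignment` (an [msa_alignment()]) and `truth` (planted calls
#'   and per-homolog target identities).
#' @export
gen_msa <- function(seed, n_homologs = 18, ref_length = 460,
                    identity_range = c(0.62, 0.95), planted_calls = NULL,
                    majority_fraction = 0.6, out_dir = NULL) {
  n_planted <- if (is.null(planted_calls)) 0 else nrow(planted_calls)
  if (n_planted > 0) {
    stopifnot(all(c("position", "wt", "consensus") %in% names(planted_calls)),
              !anyDuplicated(planted_calls$position),
              all(planted_calls$position >= 1),
              all(planted_calls$position <= ref_length),
              all(planted_calls$wt != planted_calls$consensus))
  }
  min_mismatch <- round((1 - identity_range[2]) * ref_length)
  if (n_planted > min_mismatch)
    stop("infeasible-spec: ", n_planted, " planted positions exceed the ",
         min_mismatch, " mismatches allowed at identity ", identity_range[2])
  res <- with_seed(seed, {
    ref <- sample(AA20, ref_length, replace = TRUE)
    if (n_planted > 0) ref[planted_calls$position] <- planted_calls$wt
    n_major <- ceiling(majority_fraction * n_homologs)
    ## which homologs carry the consensus residue at each planted position
    carriers <- lapply(seq_len(n_planted), function(i)
      sample(n_homologs, n_major))
    targets <- stats::runif(n_homologs, identity_range[1], identity_range[2])
    free_pos <- setdiff(seq_len(ref_length),
                        if (n_planted > 0) planted_calls$position else integer())
    seqs <- vapply(seq_len(n_homologs), function(h) {
      s <- ref
      if (n_planted > 0) {
        for (i in seq_len(n_planted)) {
          pos <- planted_calls$position[i]
          if (h %in% carriers[[i]]) {
            s[pos] <- planted_calls$consensus[i]
          } else {
            s[pos] <- sample(setdiff(AA20, c(planted_calls$wt[i],
                                             planted_calls$consensus[i])), 1)
          }
        }
      }
      m_total <- round((1 - targets[h]) * ref_length)
      m_extra <- max(m_total - n_planted, 0)
      mut_pos <- sample(free_pos, m_extra)
      for (pos in mut_pos) s[pos] <- sample(setdiff(AA20, ref[pos]), 1)
      paste(s, collapse = "")
    }, character(1))
    list(ref = paste(ref, collapse = ""), seqs = seqs, targets = targets)
  })
  ids <- c("REF", sprintf("HOM%02d", seq_len(n_homologs)))
  aln <- msa_alignment(ids, c(res$ref, res$seqs), "REF")
  truth <- list(
    seed = seed, n_homologs = n_homologs, ref_length = ref_length,
    majority_fraction = majority_fraction,
    target_identities = res$targets,
    planted_calls = if (n_planted > 0) planted_calls else list()
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_alignment(aln, file.path(out_dir, "msa.fasta"))
    write_truth_sidecar(truth, file.path(out_dir, "msa_truth.json"))
  }
  list(alignment = aln, truth = truth)
}

## ideal disulfide-bridged residue pair built from internal coordinates;
## chi1 = -60 on both residues (a scan grid point), chi3 and the S-S
## distance as requested. Returns an atom data frame for the two residues.
ideal_ss_pair_atoms <- function(chain, resno_i, resno_j, d_sg = SS_TARGET_D,
                                chi3 = SS_CHI3_IDEAL, chi1 = -60,
                                origin = c(0, 0, 0)) {
  sg1 <- c(0, 0, 0)
  sg2 <- c(d_sg, 0, 0)
  ang <- 104 * pi / 180
  cb1 <- sg1 + SS_BOND_SG * c(cos(ang), sin(ang), 0)
  cb2 <- as.numeric(place_atom(cb1, sg1, sg2, SS_BOND_SG, 104, chi3))
  build_res <- function(sg_far, sg_own, cb) {
    ca <- as.numeric(place_atom(sg_far, sg_own, cb, 1.53, SS_ANGLE_CB_SG, 180))
    n <- as.numeric(place_atom(sg_own, cb, ca, 1.46, 110.5, chi1))
    cc <- as.numeric(place_atom(cb, n, ca, 1.52, 111, 120))
    rbind(N = n, CA = ca, CB = cb, C = cc)
  }
  r1 <- build_res(sg2, sg1, cb1)
  r2 <- build_res(sg1, sg2, cb2)
  mk <- function(m, resno) data.frame(
    chain = chain, resno = resno, resid = "CYS",
    elety = rownames(m),
    x = m[, 1] + origin[1], y = m[, 2] + origin[2], z = m[, 3] + origin[3],
    b = 20, stringsAsFactors = FALSE)
  rbind(mk(r1, resno_i), mk(r2, resno_j))
}

#' Generate a synthetic structure with plantable screen signals
#'
#' Builds an extended poly-alanine backbone, repositions planted residue
#' pairs to ideal disulfide geometry (S-S 2.05 A, chi3 87 deg, chi1 on the
#' scan grid), and lays Gaussian B-factor bumps (peak `b_peak` over baseline
#' `b_base`) across hotspot residue ranges.
#'
#' @param seed integer seed.
#' @param n_res number of residues (default 60).
#' @param chain chain identifier (default "A").
#' @param planted_ss_pairs list of integer pairs `c(i, j)` (|i - j| >= 3).
#' @param b_hotspots list of integer ranges `c(start, end)`.
#' @param b_base baseline B-factor (default 20).
#' @param b_peak hotspot bump height (default 30).
#' @param b_noise_sd Gaussian B-factor noise SD (default 0.8).
#' @param out_dir optional directory: writes `structure.pdb` plus
#'   `structure_truth.json`.
#' @return List `structure` (a `pdb_structure`) and `truth`.
#' @export
gen_structure <- function(seed, n_res = 60, chain = "A",
                          planted_ss_pairs = list(), b_hotspots = list(),
                          b_base = 20, b_peak = 30, b_noise_sd = 0.8,
                          out_dir = NULL) {
  for (p in planted_ss_pairs) {
    stopifnot(length(p) == 2, all(p >= 1), all(p <= n_res))
    if (abs(p[1] - p[2]) < 3)
      stop("infeasible geometry: planted pair closer than min separation")
  }
  atoms <- with_seed(seed, {
    rows <- lapply(seq_len(n_res), function(r) {
      x0 <- 3.5 * r
      zig <- (-1)^r
      n <- c(x0, 0.4 * zig, 0.1)
      ca <- c(x0 + 1.2, 0.9 * zig, 0.3 * zig)
      cc <- c(x0 + 2.4, 0.2 * zig, -0.2)
      cb <- reconstruct_cb(n, ca, cc)
      data.frame(chain = chain, resno = r, resid = "ALA",
                 elety = c("N", "CA", "CB", "C"),
                 x = c(n[1], ca[1], cb[1], cc[1]),
                 y = c(n[2], ca[2], cb[2], cc[2]),
                 z = c(n[3], ca[3], cb[3], cc[3]),
                 b = b_base, stringsAsFactors = FALSE)
    })
    at <- do.call(rbind, rows)
    ## replace planted pairs with ideal disulfide geometry, placed well away
    ## from the chain so no incidental contacts arise
    for (k in seq_along(planted_ss_pairs)) {
      p <- planted_ss_pairs[[k]]
      pair <- ideal_ss_pair_atoms(chain, p[1], p[2],
                                  origin = c(0, 100 + 20 * k, 50))
      at <- at[!(at$resno %in% p), ]
      at <- rbind(at, pair)
    }
    at <- at[order(at$resno, match(at$elety, c("N", "CA", "CB", "C"))), ]
    ## B-factor profile: baseline with high-frequency wobble (so sliding-
    ## window z means stay near zero away from hotspots) + noise + bumps
    b <- b_base + 0.8 * b_noise_sd * (-1)^seq_len(n_res) +
      stats::rnorm(n_res, 0, 0.2 * b_noise_sd)
    for (h in b_hotspots) {
      ctr <- mean(h)
      wid <- max((h[2] - h[1]) / 2, 1)
      b <- b + b_peak * exp(-((seq_len(n_res) - ctr) / wid)^2)
    }
    at$b <- b[at$resno]
    at
  })
  st <- pdb_structure(atoms)
  truth <- list(seed = seed, n_res = n_res, chain = chain,
                planted_ss_pairs = planted_ss_pairs, b_hotspots = b_hotspots,
                b_base = b_base, b_peak = b_peak)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_structure(st, file.path(out_dir, "structure.pdb"))
    write_truth_sidecar(truth, file.path(out_dir, "structure_truth.json"))
  }
  list(structure = st, truth = truth)
}

#' Generate DSF melt curves
#'
#' Boltzmann sigmoid plus baseline plus Gaussian noise over a 25-99 C ramp,
#' matching the DSF protocol's temperature range.
#'
#' @param seed integer seed.
#' @param variants data frame `name`, `tm`, `slope` (true parameters).
#' @param replicates replicates per variant (default 3).
#' @param noise_sd Gaussian noise SD as a fraction of amplitude (default
#'   0.02).
#' @param grid temperature grid (default 25-99 C in 0.5 C steps).
#' @param baseline pre-transition fluorescence (default 0.1).
#' @param amplitude transition amplitude (default 1).
#' @param out_dir optional directory: writes `melt_curves.csv` plus
#'   `melt_truth.json`.
#' @return List `curves` (list of [melt_curve()]), `table` (long data frame
#'   `variant`, `replicate`, `temperature_C`, `fluorescence`), `truth`.
#' @export
gen_melt_curves <- function(seed, variants, replicates = 3, noise_sd = 0.02,
                            grid = seq(25, 99, by = 0.5), baseline = 0.1,
                            amplitude = 1, out_dir = NULL) {
  stopifnot(all(c("name", "tm", "slope") %in% names(variants)))
  if (any(variants$tm <= min(grid)) || any(variants$tm >= max(grid)))
    stop("true Tm outside the temperature grid")
  curves <- with_seed(seed, {
    out <- list()
    for (i in seq_len(nrow(variants))) {
      for (rep_id in seq_len(replicates)) {
        mu <- baseline + amplitude /
          (1 + exp((variants$tm[i] - grid) / variants$slope[i]))
        f <- mu + stats::rnorm(length(grid), 0, noise_sd * amplitude)
        out[[length(out) + 1]] <- melt_curve(grid, f,
                                             variant = variants$name[i],
                                             replicate = rep_id)
      }
    }
    out
  })
  tab <- do.call(rbind, lapply(curves, function(cv) {
    data.frame(variant = attr(cv, "variant"),
               replicate = attr(cv, "replicate"),
               temperature_C = cv$temperature,
               fluorescence = cv$fluorescence, stringsAsFactors = FALSE)
  }))
  truth <- list(seed = seed, variants = variants, replicates = replicates,
                noise_sd = noise_sd, baseline = baseline,
                amplitude = amplitude)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(tab, file.path(out_dir, "melt_curves.csv"),
                     row.names = FALSE)
    write_truth_sidecar(truth, file.path(out_dir, "melt_truth.json"))
  }
  list(curves = curves, table = tab, truth = truth)
}

#' Generate a first-order decay curve
#'
#' @param seed integer seed.
#' @param k true rate constant (per hour).
#' @param a0 initial amplitude (default 100).
#' @param timepoints sampling times in hours (default 0-6 h, 13 points).
#' @param noise_sd Gaussian noise SD as a fraction of `a0` (default 0.05).
#' @param kind signal kind (default `"peak_area"`).
#' @param out_dir optional directory: writes `decay.csv` plus
#'   `decay_truth.json`.
#' @return List `curve` (a [progress_curve()]) and `truth`.
#' @export
gen_decay <- function(seed, k = 0.5, a0 = 100,
                      timepoints = seq(0, 6, by = 0.5), noise_sd = 0.05,
                      kind = "peak_area", out_dir = NULL) {
  stopifnot(k >= 0, a0 > 0)
  sig <- with_seed(seed, {
    mu <- a0 * exp(-k * timepoints)
    pmax(mu + stats::rnorm(length(mu), 0, noise_sd * a0), 0)
  })
  if (sig[1] <= 0) sig[1] <- a0 * 1e-6  # keep t = 0 usable for normalization
  curve <- progress_curve(timepoints, sig, kind = kind)
  truth <- list(seed = seed, k = k, a0 = a0, noise_sd = noise_sd)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(data.frame(time_h = timepoints, signal = sig,
                                kind = kind),
                     file.path(out_dir, "decay.csv"), row.names = FALSE)
    write_truth_sidecar(truth, file.path(out_dir, "decay_truth.json"))
  }
  list(curve = curve, truth = truth)
}

#' Generate synthetic price distributions
#'
#' Defaults to triangular distributions centred on the listed price with a
#' +/- `span` support, for the items whose market prices carry the most
#' uncertainty.
#'
#' @param seed integer seed.
#' @param prices a [price_table()] (default [default_price_table()]).
#' @param items items to randomize (default enzymes, sucrose, indoxyl).
#' @param family distribution family (default `"triangular"`).
#' @param span relative half-width (default 0.5).
#' @param n_sample draws per item for the sampled table (default 1000).
#' @param out_dir optional directory: writes `price_samples.csv` plus
#'   `prices_truth.json`.
#' @return List `distributions` (list of [price_distribution()]), `samples`
#'   (data frame item x draws, long), `truth`.
#' @export
gen_price_distributions <- function(seed, prices = default_price_table(),
                                    items = c("enzymes", "sucrose",
                                              "indoxyl"),
                                    family = "triangular", span = 0.5,
                                    n_sample = 1000, out_dir = NULL) {
  idx <- match(items, prices$item)
  if (anyNA(idx)) stop("unknown items: ",
                       paste(items[is.na(idx)], collapse = ", "))
  dists <- lapply(seq_along(items), function(i) {
    p <- prices$price[idx[i]]
    switch(family,
      point = price_distribution(items[i], "point", value = p),
      uniform = price_distribution(items[i], "uniform",
                                   min = p * (1 - span),
                                   max = p * (1 + span)),
      triangular = price_distribution(items[i], "triangular",
                                      min = p * (1 - span), mode = p,
                                      max = p * (1 + span)),
      lognormal = price_distribution(items[i], "lognormal",
                                     meanlog = log(p), sdlog = span / 2),
      stop("unknown family: ", family))
  })
  samples <- with_seed(seed, {
    do.call(rbind, lapply(dists, function(d)
      data.frame(item = d$item,
                 draw = seq_len(n_sample),
                 price = sample_price_distribution(d, n_sample),
                 stringsAsFactors = FALSE)))
  })
  truth <- list(seed = seed, items = items, family = family, span = span,
                base_prices = prices$price[idx])
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(samples, file.path(out_dir, "price_samples.csv"),
                     row.names = FALSE)
    write_truth_sidecar(truth, file.path(out_dir, "prices_truth.json"))
  }
  list(distributions = dists, samples = samples, truth = truth)
}

#' Generate reflectance spectra
#'
#' Smooth template curves: `denim_blue` (reflectance rising toward the blue,
#' guaranteeing b* < 0 at the default depth), `undyed` (bright, slightly
#' warm) and `gray` (spectrally flat 18%).
#'
#' @param seed integer seed.
#' @param template one of `"denim_blue"`, `"undyed"`, `"gray"`.
#' @param depth dye depth parameter >= 1 (darker with depth; default 1).
#' @param noise_sd additive Gaussian noise SD (default 0.003).
#' @param n_spectra number of replicate spectra (default 1).
#' @param grid wavelength grid (default 400-700 nm, 5 nm).
#' @param out_dir optional directory: writes `spectra.csv` (long format) plus
#'   `spectra_truth.json`.
#' @return List `spectra` (list of [reflectance_spectrum()]), `truth`.
#' @export
gen_reflectance <- function(seed, template = c("denim_blue", "undyed",
                                               "gray"),
                            depth = 1, noise_sd = 0.003, n_spectra = 1,
                            grid = seq(400, 700, by = 5), out_dir = NULL) {
  template <- match.arg(template)
  stopifnot(depth >= 1)
  base <- switch(template,
    denim_blue = (0.08 + 0.30 * exp(-((grid - 450) / 70)^2))^depth,
    undyed = pmin(0.60 + 0.0005 * (grid - 400), 1),
    gray = rep(0.18, length(grid)))
  spectra <- with_seed(seed, {
    lapply(seq_len(n_spectra), function(i) {
      r <- pmin(pmax(base + stats::rnorm(length(grid), 0, noise_sd), 0), 1.05)
      reflectance_spectrum(grid, r)
    })
  })
  truth <- list(seed = seed, template = template, depth = depth,
                noise_sd = noise_sd)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    tab <- do.call(rbind, lapply(seq_along(spectra), function(i)
      data.frame(sample = i, wavelength_nm = spectra[[i]]$wavelength,
                 reflectance = spectra[[i]]$reflectance)))
    utils::write.csv(tab, file.path(out_dir, "spectra.csv"),
                     row.names = FALSE)
    write_truth_sidecar(truth, file.path(out_dir, "spectra_truth.json"))
  }
  list(spectra = spectra, truth = truth)
}
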