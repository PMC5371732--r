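#' Solve the liver network for every subject of a cohort
#'
#' Assembles each subject's personalized exchange bounds, applies them to the
#' network, and solves either by flux-sum minimization (\code{"min_sum"},
#' default, the parsimonious assumption) or by hit-and-run sampling with the
#' per-subject sample mean reported (\code{"sampled_mean"}). Failed solves are
#' recorded per subject with their status; there is never partial silent
#' output.
#'
#' @param cohort a \code{liver_cohort} data.frame.
#' @param network a \code{metabolic_network} (bounds are applied per subject).
#' @param mode \code{"min_sum"} or \code{"sampled_mean"}.
#' @param seed RNG seed (sampling mode; subject i uses \code{seed + i}).
#' @param n_samples samples per subject in sampling mode.
#' @param profiles,const forwarded to [assemble_subject_bounds()].
#' @param bounds_override optional function \code{(bounds, subject) -> bounds}
#'   applied after assembly (used by the randomized-input control).
#' @return object of class \code{flux_matrix}: list with \code{fluxes}
#'   (subjects x reactions, NA rows for failures), \code{status} per subject,
#'   \code{mode} and the subject ids.
#' @export
solve_cohort <- function(cohort, network, mode = c("min_sum", "sampled_mean"),
                         seed = 1, n_samples = 100,
                         profiles = aa_profiles(),
                         const = physiology_constants(),
                         bounds_override = NULL) {
  mode <- match.arg(mode)
  n <- nrow(cohort)
  fluxes <- matrix(NA_real_, n, nrow(network$reactions),
                   dimnames = list(cohort$id, network$reactions$id))
  status <- character(n)
  for (i in seq_len(n)) {
    eb <- assemble_subject_bounds(cohort[i, ], profiles, const)
    if (!is.null(bounds_override)) eb <- bounds_override(eb, cohort[i, ])
    nb <- apply_bounds(network, eb)
    if (mode == "min_sum") {
      sol <- minimize_flux_sum(nb)
      status[i] <- sol$status
      if (sol$status == "optimal") fluxes[i, ] <- sol$fluxes
    } else {
      res <- tryCatch(sample_fluxes(nb, n = n_samples, seed = seed + i),
                      error = function(e) e)
      if (inherits(res, "error")) {
        status[i] <- conditionMessage(res)
      } else {
        status[i] <- "optimal"
        fluxes[i, ] <- colMeans(res$samples)
      }
    }
  }
  structure(list(fluxes = fluxes, status = status, mode = mode,
                 ids = cohort$id), class = "flux_matrix")
}

#' Net fat influx of a flux solution
#'
#' Net fat influx (NFI) is the fatty-acid uptake minus the fatty-acid
#' secretion of the solved liver model, in mmol FA-equivalents/h. Secreted
#' VLDL triglyceride is converted to FA equivalents with the configured TG:FA
#' stoichiometry (default 3). Boundary reactions are identified by their
#' metabolite tags (\code{fa} uptake, \code{vldl_tg} secretion).
#'
#' @param fluxes a named flux vector, or a \code{flux_matrix} (then one NFI
#'   per subject is returned, NA for failed solves).
#' @param network the network the fluxes belong to.
#' @param const physiology constants (\code{tg_fa_stoich}).
#' @return numeric NFI value(s), mmol FA-equivalents/h.
#' @export
net_fat_influx <- function(fluxes, network, const = physiology_constants()) {
  rx <- network$reactions
  fa_up <- rx$id[!is.na(rx$bnd_metabolite) & rx$bnd_metabolite == "fa" &
                   rx$bnd_direction == "uptake"]
  tg_sec <- rx$id[!is.na(rx$bnd_metabolite) & rx$bnd_metabolite == "vldl_tg" &
                    rx$bnd_direction == "secretion"]
  if (length(fa_up) != 1 || length(tg_sec) != 1)
    stop("network lacks tagged FA-uptake / VLDL-TG-secretion boundary reactions")
  if (inherits(fluxes, "flux_matrix")) {
    fluxes$fluxes[, fa_up] - const$tg_fa_stoich * fluxes$fluxes[, tg_sec]
  } else {
    unname(fluxes[fa_up] - const$tg_fa_stoich * fluxes[tg_sec])
  }
}

#' Correlate per-reaction fluxes with a phenotype
#'
#' Pearson correlation and two-sided p-value (t-distribution transform) of
#' every reaction's flux across subjects against a phenotype vector (e.g.
#' liver fat or NFI). Subjects with failed solves or missing phenotype are
#' excluded pairwise and the n actually used is reported. Constant flux
#' columns are reported with \code{NA} correlation and flagged as undefined
#' rather than forced to zero.
#'
#' @param flux_matrix a \code{flux_matrix}.
#' @param phenotype numeric vector, one value per cohort subject.
#' @param phenotype_name label stored in the output.
#' @return data.frame of class \code{association_table}: reaction, subsystem,
#'   r, p, n, note.
#' @export
correlate_fluxes <- function(flux_matrix, phenotype,
                             phenotype_name = "phenotype") {
  F <- flux_matrix$fluxes
  if (length(phenotype) != nrow(F))
    stop("phenotype length must equal cohort size")
  keep <- flux_matrix$status == "optimal" & is.finite(phenotype)
  if (sum(keep) < 3) stop("fewer than 3 usable subjects")
  F <- F[keep, , drop = FALSE]
  ph <- phenotype[keep]
  res <- lapply(colnames(F), function(j) {
    x <- F[, j]
    if (stats::sd(x) < 1e-12)
      return(data.frame(reaction = j, r = NA_real_, p = NA_real_,
                        n = length(x), note = "constant flux",
                        stringsAsFactors = FALSE))
    ct <- stats::cor.test(x, ph)
    data.frame(reaction = j, r = unname(ct$estimate), p = ct$p.value,
               n = length(x), note = "", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  attr(out, "phenotype") <- phenotype_name
  class(out) <- c("association_table", "data.frame")
  out
}

#' Build a bounds override replacing personalized inputs/outputs
#'
#' Returns a \code{bounds_override} function for [solve_cohort()] that
#' substitutes the per-subject FA uptake (with its coupled glycerol release)
#' and/or the measured VLDL-TG and apoB secretion with the supplied draws.
#' Quantities not selected by \code{randomize} are left untouched.
#'
#' @param randomize \code{"fa"}, \code{"vldl"} or \code{"both"}.
#' @param ids cohort subject ids, aligned with the draw vectors.
#' @param fa_draw,tg_draw,apob_draw replacement rates per subject (mmol/h).
#' @param const physiology constants.
#' @return function \code{(bounds, subject) -> bounds}.
#' @export
randomized_bounds_override <- function(randomize, ids, fa_draw, tg_draw,
                                       apob_draw,
                                       const = physiology_constants()) {
  force(randomize); force(ids)
  function(eb, subject) {
    i <- match(subject$id, ids)
    if (randomize %in% c("fa", "both")) {
      sel <- eb$metabolite == "fa" & eb$direction == "uptake"
      eb$lower[sel] <- eb$upper[sel] <- fa_draw[i]
      sel <- eb$metabolite == "glycerol" & eb$direction == "uptake"
      eb$lower[sel] <- eb$upper[sel] <- fa_draw[i] / const$glycerol_to_fa_ratio
    }
    if (randomize %in% c("vldl", "both")) {
      sel <- eb$metabolite == "vldl_tg" & eb$direction == "secretion"
      eb$lower[sel] <- eb$upper[sel] <- tg_draw[i]
      sel <- eb$metabolite == "apob" & eb$direction == "secretion"
      eb$lower[sel] <- eb$upper[sel] <- apob_draw[i]
    }
    eb
  }
}

#' Randomized-input control analysis
#'
#' Tests whether the flux-phenotype correlations are driven by the
#' personalized inputs and outputs: per repetition, the personalized FA
#' uptake and/or the measured VLDL secretion (TG and apoB) of every subject
#' are replaced by uniform draws over the cohort minimum-maximum range, the
#' cohort is re-solved, and the correlations of the redox reactions (NNT,
#' GSR, GPX) with liver fat and with NFI are recomputed.
#'
#' @param cohort a \code{liver_cohort}.
#' @param network a \code{metabolic_network}.
#' @param randomize \code{"fa"}, \code{"vldl"} or \code{"both"}.
#' @param reps number of randomization repetitions (>= 1).
#' @param seed RNG seed.
#' @param reactions reaction ids whose correlations are tracked.
#' @param profiles,const forwarded to the per-subject bound assembly.
#' @param max_resample cap on infeasible-draw retries per repetition.
#' @return list with \code{per_rep} (data.frame: rep, reaction, r_hs, r_nfi),
#'   \code{real} (the same correlations under the true personalized inputs)
#'   and \code{n_failed} solve failures encountered.
#' @export
random_control <- function(cohort, network, randomize = c("both", "fa", "vldl"),
                           reps = 20, seed = 1,
                           reactions = c("NNT", "GSR", "GPX"),
                           profiles = aa_profiles(),
                           const = physiology_constants(),
                           max_resample = 5) {
  randomize <- match.arg(randomize)
  stopifnot(reps >= 1)
  fat <- ifelse(is.finite(cohort$fat_mass), cohort$fat_mass,
                fat_mass_from_bmi(cohort$bmi))
  fa_rates <- const$fa_release_mmol_h_kg * fat
  rng_fa <- range(fa_rates)
  rng_tg <- range(cohort$vldl_tg_secretion)
  rng_apob <- range(cohort$vldl_apob_secretion)

  corr_for <- function(fm) {
    nfi <- net_fat_influx(fm, network, const)
    hs_tab <- correlate_fluxes(fm, cohort$liver_fat_pct, "HS")
    nfi_tab <- correlate_fluxes(fm, nfi, "NFI")
    data.frame(reaction = reactions,
               r_hs = hs_tab$r[match(reactions, hs_tab$reaction)],
               r_nfi = nfi_tab$r[match(reactions, nfi_tab$reaction)],
               stringsAsFactors = FALSE)
  }

  real_fm <- solve_cohort(cohort, network, "min_sum",
                          profiles = profiles, const = const)
  real <- corr_for(real_fm)

  set.seed(seed)
  n <- nrow(cohort)
  per_rep <- vector("list", reps)
  n_failed <- 0L
  for (r in seq_len(reps)) {
    for (attempt in seq_len(max_resample)) {
      fa_draw <- stats::runif(n, rng_fa[1], rng_fa[2])
      tg_draw <- stats::runif(n, rng_tg[1], rng_tg[2])
      apob_draw <- stats::runif(n, rng_apob[1], rng_apob[2])
      override <- randomized_bounds_override(randomize, cohort$id, fa_draw,
                                             tg_draw, apob_draw, const)
      fm <- solve_cohort(cohort, network, "min_sum", profiles = profiles,
                         const = const, bounds_override = override)
      if (all(fm$status == "optimal")) break
      n_failed <- n_failed + sum(fm$status != "optimal")
    }
    pr <- corr_for(fm)
    pr$rep <- r
    per_rep[[r]] <- pr
  }
  list(per_rep = do.call(rbind, per_rep), real = real, n_failed = n_failed)
}
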