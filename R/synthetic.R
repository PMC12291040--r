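#' Define a synthetic NPS class template
#'
#' A template describes one drug class's statistical footprint in the
#' 8-variable feature space: a precursor-mass window, a retention-time
#' window, a set of characteristic neutral losses with occurrence
#' probabilities (fragments are generated as precursor minus loss, so
#' classes cluster in the neutral-loss columns), low-intensity extra
#' fragments, and jitter/missingness controls.  Templates emulate the
#' class-clustered geometry of real screening panels, not
#' fragmentation chemistry.
#'
#' @param class_label class name.
#' @param precursor_range,rt_range numeric `(min, max)` windows (Th,
#'   minutes); must be non-degenerate.
#' @param losses named or unnamed numeric vector of characteristic
#'   neutral losses (Da), listed in decreasing expected intensity.
#' @param loss_prob occurrence probability per loss (recycled).
#' @param n_extra_fragments integer `(min, max)` count of uninformative
#'   low-intensity fragments per spectrum.
#' @param intensity_concentration gamma shape controlling how evenly
#'   intensity spreads over the characteristic fragments (larger =
#'   more even).
#' @param missing_fragment_prob probability that a non-base
#'   characteristic fragment is absent from a spectrum.
#' @param loss_sd per-analyte standard deviation (Da) of each
#'   characteristic loss around its template value, emulating the
#'   homologue spread (alkyl-chain and substituent variation) within a
#'   drug class; 0 makes every analyte share exact losses.
#' @param mz_noise_sd,rt_noise_sd jitter standard deviations for
#'   fragment/precursor m/z (Th) and retention time (min).
#' @return object of class `class_template`.
#' @export
class_template <- function(class_label, precursor_range, rt_range, losses,
                           loss_prob = 1, n_extra_fragments = c(1L, 3L),
                           intensity_concentration = 4,
                           missing_fragment_prob = 0, loss_sd = 0,
                           mz_noise_sd = 0.002, rt_noise_sd = 0.03) {
  stopifnot(length(precursor_range) == 2L, diff(precursor_range) > 0,
            length(rt_range) == 2L, diff(rt_range) > 0,
            length(losses) >= 1L, all(losses > 0),
            all(loss_prob >= 0 & loss_prob <= 1),
            missing_fragment_prob >= 0, missing_fragment_prob <= 1)
  structure(list(class_label = class_label,
                 precursor_range = as.numeric(precursor_range),
                 rt_range = as.numeric(rt_range),
                 losses = as.numeric(losses),
                 loss_prob = rep_len(as.numeric(loss_prob), length(losses)),
                 n_extra_fragments = as.integer(rep_len(n_extra_fragments, 2L)),
                 intensity_concentration = intensity_concentration,
                 missing_fragment_prob = missing_fragment_prob,
                 loss_sd = loss_sd,
                 mz_noise_sd = mz_noise_sd, rt_noise_sd = rt_noise_sd),
            class = "class_template")
}

#' Generate a seeded synthetic spectra panel
#'
#' Draws `n_per_class` spectra per template from a single seeded RNG
#' stream: precursor and retention time uniform in the template
#' windows, characteristic fragments at precursor minus loss (Gaussian
#' m/z jitter), intensities from a gamma spread with the template's
#' concentration (characteristic fragments rank in template order, the
#' first being the base peak), plus low-intensity extra fragments that
#' fall below a 10 percent relative-intensity threshold.  Regenerating
#' with the same seed and templates reproduces the panel bit-for-bit.
#'
#' @param templates list of [class_template()] objects (non-empty).
#' @param n_per_class records per template: a scalar or a vector
#'   recycled along templates.
#' @param seed integer RNG seed (mandatory: panels are reproducible by
#'   construction).
#' @return object of class `synthetic_panel`: `records` (list of
#'   [spectrum_record()]), `truth` (data.frame `analyte_id,
#'   class_label`), `seed`.
#' @export
generate_panel <- function(templates, n_per_class, seed) {
  if (!length(templates)) stop("template list is empty")
  if (inherits(templates, "class_template")) templates <- list(templates)
  stopifnot(all(vapply(templates, inherits, TRUE, "class_template")),
            all(n_per_class >= 1L), !missing(seed))
  n_per_class <- rep_len(as.integer(n_per_class), length(templates))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  records <- list()
  for (ti in seq_along(templates)) {
    tp <- templates[[ti]]
    for (i in seq_len(n_per_class[ti])) {
      prec <- stats::runif(1, tp$precursor_range[1L], tp$precursor_range[2L])
      rt <- max(0, stats::runif(1, tp$rt_range[1L], tp$rt_range[2L]) +
                  stats::rnorm(1, 0, tp$rt_noise_sd))
      present <- stats::runif(length(tp$losses)) < tp$loss_prob
      if (length(tp$losses) > 1L) {
        drop <- stats::runif(length(tp$losses)) < tp$missing_fragment_prob
        drop[1L] <- FALSE  # the base-peak fragment is always present
        present <- present & !drop
      }
      if (!any(present)) present[1L] <- TRUE
      k <- sum(present)
      # per-analyte homologue deviation of the characteristic losses,
      # on top of the (much smaller) mass-measurement jitter
      losses_i <- tp$losses[present] + stats::rnorm(k, 0, tp$loss_sd)
      frag_mz <- pmax(20, prec - losses_i +
                        stats::rnorm(k, 0, tp$mz_noise_sd))
      w <- sort(stats::rgamma(k, shape = tp$intensity_concentration),
                decreasing = TRUE)
      frag_int <- 1000 * w / w[1L]
      extra_choices <- seq(tp$n_extra_fragments[1L], tp$n_extra_fragments[2L])
      n_extra <- extra_choices[sample.int(length(extra_choices), 1L)]
      if (n_extra > 0L) {
        extra_mz <- stats::runif(n_extra, 50, max(60, prec - 5))
        extra_int <- stats::runif(n_extra, 2, 80)  # < 10% of the base peak
        frag_mz <- c(frag_mz, extra_mz)
        frag_int <- c(frag_int, extra_int)
      }
      records[[length(records) + 1L]] <- spectrum_record(
        analyte_id = sprintf("%s_%03d", tp$class_label, i),
        precursor_mz = prec, rt_min = rt,
        peaks = cbind(frag_mz, frag_int),
        class_label = tp$class_label)
    }
  }
  truth <- data.frame(
    analyte_id = vapply(records, `[[`, "", "analyte_id"),
    class_label = vapply(records, `[[`, "", "class_label"),
    stringsAsFactors = FALSE)
  structure(list(records = records, truth = truth, seed = as.integer(seed)),
            class = "synthetic_panel")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' @export
print.synthetic_panel <- function(x, ...) {
  cat(sprintf("<synthetic_panel> %d records, %d classes, seed = %d\n",
              nrow(x$truth), length(unique(x$truth$class_label)), x$seed))
  invisible(x)
}

#' Draw a feature matrix directly from multivariate normals
#'
#' Bypasses spectrum generation: samples each class straight from a
#' multivariate normal in the 8-variable space.  Used for calibration
#' tests where exact Gaussian class structure is wanted.
#'
#' @param means class-by-variable matrix of class means (rownames are
#'   the class labels) or a list of mean vectors.
#' @param covs a single covariance matrix shared by all classes, or a
#'   list per class; must be symmetric positive semi-definite
#'   (rank-deficient covariances are allowed and sampled on their
#'   support).
#' @param n_per_class samples per class (scalar or vector).
#' @param seed integer RNG seed.
#' @return a `feature_matrix` with `class_label` set per generating
#'   class.
#' @export
generate_feature_matrix <- function(means, covs = NULL, n_per_class, seed) {
  if (is.list(means)) means <- do.call(rbind, means)
  means <- as.matrix(means)
  p <- ncol(means)
  labels <- rownames(means)
  if (is.null(labels)) labels <- sprintf("class_%d", seq_len(nrow(means)))
  if (is.null(covs)) covs <- diag(p)
  if (!is.list(covs)) covs <- rep(list(covs), nrow(means))
  stopifnot(length(covs) == nrow(means), !missing(seed))
  n_per_class <- rep_len(as.integer(n_per_class), nrow(means))
  roots <- lapply(covs, function(S) {
    S <- as.matrix(S)
    if (!isTRUE(all.equal(S, t(S), tolerance = 1e-8))) {
      stop("covariance matrix is not symmetric")
    }
    e <- eigen((S + t(S)) / 2, symmetric = TRUE)
    if (any(e$values < -1e-8 * max(abs(e$values), 1))) {
      stop("covariance matrix is not positive semi-definite")
    }
    e$vectors %*% diag(sqrt(pmax(e$values, 0)), p)
  })
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  rows <- vector("list", nrow(means))
  for (ci in seq_len(nrow(means))) {
    z <- matrix(stats::rnorm(n_per_class[ci] * p), n_per_class[ci], p)
    rows[[ci]] <- sweep(z %*% t(roots[[ci]]), 2L, means[ci, ], "+")
  }
  feature_matrix(do.call(rbind, rows),
                 class_label = rep(labels, n_per_class))
}

#' Default synthetic class templates
#'
#' Nine templates named after the drug classes commonly modeled in
#' forensic NPS screening panels (benzodiazepines, cathinones,
#' fentanyls, JWH, nitazenes, PINACA, tryptamines,
#' arylcyclohexylamines, phenethylamines), plus an optional broad
#' `other_nps` background template.  All numeric values are invented:
#' they reproduce the statistical geometry such panels show —
#' class-specific precursor and retention windows, shared neutral
#' losses between the structurally related JWH/PINACA pair (a common
#' indole-alkyl fragment) and between cathinones and phenethylamines —
#' not the chemistry of any real compound.
#'
#' @param include_other add the dispersed `other_nps` background
#'   template (so the default panel sizes total 159 analytes).
#' @return named list of [class_template()] objects.
#' @seealso [default_panel_sizes()], [separated_templates()],
#'   [no_nps_template()]
#' @export
default_templates <- function(include_other = TRUE) {
  shared_cannabinoid <- 155.0491  # indole-alkyl-type loss shared by JWH/PINACA
  tpl <- list(
    class_template("arylcyclohexylamines", c(222, 278), c(3.5, 5.0),
                   c(18.0106, 83.0735, 121.0640), loss_sd = 0.5),
    class_template("benzodiazepines", c(281, 319), c(4.0, 6.0),
                   c(26.0030, 28.0062, 69.0215), loss_sd = 0.5),
    class_template("cathinones", c(150, 248), c(1.5, 3.5),
                   c(18.0106, 46.0419, 56.0626),
                   missing_fragment_prob = 0.10, loss_sd = 0.5),
    class_template("fentanyls", c(322, 418), c(4.5, 6.5),
                   c(105.0704, 146.0964, 186.1283), loss_sd = 0.5),
    class_template("JWH", c(322, 378), c(8.0, 10.0),
                   c(126.0464, shared_cannabinoid, 214.0890), loss_sd = 0.5),
    class_template("nitazenes", c(381, 419), c(5.2, 6.8),
                   c(72.0808, 100.0757, 121.0640), loss_sd = 0.5),
    class_template("PINACA", c(331, 389), c(8.2, 10.5),
                   c(shared_cannabinoid, 197.1079, 213.1028), loss_sd = 0.5),
    class_template("phenethylamines", c(136, 229), c(1.8, 3.8),
                   c(17.0265, 18.0106, 46.0419), loss_sd = 0.5),
    class_template("tryptamines", c(161, 299), c(2.0, 4.5),
                   c(17.0265, 45.0578, 58.0657), loss_sd = 0.5)
  )
  names(tpl) <- vapply(tpl, `[[`, "", "class_label")
  if (include_other) {
    tpl$other_nps <- class_template(
      "other_nps", c(152, 448), c(1.0, 10.0),
      c(18.0106, 42.0344, 91.0542, 131.0735),
      loss_prob = c(0.9, 0.6, 0.6, 0.5),
      intensity_concentration = 1.5,
      missing_fragment_prob = 0.15, loss_sd = 2,
      mz_noise_sd = 0.01, rt_noise_sd = 0.2)
  }
  tpl
}

#' Default per-class panel sizes
#'
#' Class sizes of the shipped synthetic panel: nine modeled classes of
#' 17, 22, 18, 17, 4, 17, 5, 4 and 6 analytes — exercising the same
#' small-sample regimes a real screening panel presents — plus 49
#' background analytes when the `other_nps` template is included,
#' totalling 159 records.
#'
#' @param include_other include the `other_nps` background count.
#' @return named integer vector aligned with [default_templates()].
#' @export
default_panel_sizes <- function(include_other = TRUE) {
  sizes <- c(arylcyclohexylamines = 4L, benzodiazepines = 17L,
             cathinones = 22L, fentanyls = 18L, JWH = 17L,
             nitazenes = 4L, PINACA = 17L, phenethylamines = 6L,
             tryptamines = 5L)
  if (include_other) sizes <- c(sizes, other_nps = 49L)
  sizes
}

#' Well-separated synthetic class templates
#'
#' Nine templates with pairwise-disjoint precursor windows, retention
#' windows and neutral-loss sets, and tight jitter: the
#' "well-separated" regime in which a one-class panel should recover
#' near-perfect sensitivity and specificity end to end.  Used by the
#' calibration checks; the overlapping [default_templates()] are the
#' realistic counterpart.
#'
#' @return named list of [class_template()] objects.
#' @export
separated_templates <- function() {
  labels <- c("arylcyclohexylamines", "benzodiazepines", "cathinones",
              "fentanyls", "JWH", "nitazenes", "PINACA",
              "phenethylamines", "tryptamines")
  tpl <- lapply(seq_along(labels), function(i) {
    class_template(labels[i],
                   precursor_range = c(130, 142) + 40 * (i - 1),
                   rt_range = c(1.0, 1.8) + 1.1 * (i - 1),
                   losses = c(20, 45, 70) + 7.13 * (i - 1),
                   intensity_concentration = 6, loss_sd = 1.5,
                   mz_noise_sd = 0.002, rt_noise_sd = 0.02)
  })
  names(tpl) <- labels
  tpl
}

#' Template for a sample containing no NPS
#'
#' A steroid-like background template far from every class template in
#' precursor mass, retention time and neutral losses — the synthetic
#' analogue of a seized sample containing no new psychoactive
#' substance, which a well-behaved panel should assign to no class.
#'
#' @return a [class_template()].
#' @export
no_nps_template <- function() {
  class_template("no_nps", c(560, 590), c(11.5, 12.5),
                 c(239.2, 267.5), intensity_concentration = 6)
}
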