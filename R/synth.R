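#' Configuration for the synthetic data generator
#'
#' Bundles every knob of the generator with the defaults used throughout
#' the package's tests: a genus-level birth-death chronogram, a thermal
#' preference trait evolved under lambda-scaled Brownian motion, extant
#' richness driven (optionally) by temperature, and banded mountain
#' transects with a linear temperature lapse on which a genus occurs in a
#' band exactly when the band temperature falls inside its thermal niche
#' (preference +/- breadth).
#'
#' @param seed Integer seed; the whole generated dataset is a pure
#'   function of the config, so a fixed seed gives identical output.
#' @param n_tips Number of genus tips (>= 3). Default 180.
#' @param birth,death Birth-death rates, events/Myr. Defaults 0.03/0.01.
#' @param crown_age Crown age of the chronogram, Ma. Default 400.
#' @param trait_root Root thermal preference, deg C. Default 11.
#' @param trait_sigma2 BM rate, deg C squared per Myr. Default 0.05.
#' @param trait_lambda Pagel's lambda of the generating process. Default 1.
#' @param rich_a,rich_b Richness regime: net rate `r(T) = max(0, a + b T)`
#'   so `b > 0` makes warm-adapted genera species-rich. Defaults 0/0.003.
#' @param n_gradients Number of mountain transects. Default 6.
#' @param base_temp Sea-level temperature, deg C; each gradient gets a
#'   seeded offset in `+/- base_temp_spread`. Defaults 26 and 2.
#' @param base_temp_spread See `base_temp`.
#' @param lapse Temperature lapse rate, deg C per km. Default 5.5.
#' @param max_elevation Top of each transect, m. Default 4000.
#' @param band_width Elevational band width, m (bands are identified by
#'   their midpoints). Default 250.
#' @param niche_breadth Half-width of the thermal niche, deg C. Default 3.
#' @param epiphyte_quantile Genera with thermal preference above this
#'   within-dataset quantile are labelled epiphytes (warm-adapted), the
#'   rest non-epiphytes. Default 0.5.
#' @param climate_noise_temp,climate_noise_prec Gaussian noise sd added to
#'   emitted temperature / precipitation calibration points. Defaults 0/0.
#' @param dropout Per-record dropout probability stress-testing band
#'   statistics; 0 (default) keeps occupancy fully deterministic so
#'   exhaustive oracles apply.
#' @param life_form_classes Also emit epiphyte / non-epiphyte record
#'   classes alongside `"all"`. Default `TRUE`.
#' @return A `synth_config` list.
#' @export
synth_config <- function(seed = 1L, n_tips = 180L, birth = 0.03,
                         death = 0.01, crown_age = 400,
                         trait_root = 11, trait_sigma2 = 0.05,
                         trait_lambda = 1,
                         rich_a = 0, rich_b = 0.003,
                         n_gradients = 6L, base_temp = 26,
                         base_temp_spread = 2, lapse = 5.5,
                         max_elevation = 4000, band_width = 250,
                         niche_breadth = 3, epiphyte_quantile = 0.5,
                         climate_noise_temp = 0, climate_noise_prec = 0,
                         dropout = 0, life_form_classes = TRUE) {
  stopifnot(n_tips >= 3L, birth >= 0, death >= 0, crown_age > 0,
            trait_sigma2 >= 0, trait_lambda >= 0, trait_lambda <= 1,
            n_gradients >= 1L, band_width > 0, niche_breadth > 0,
            dropout >= 0, dropout < 1)
  cfg <- as.list(environment())
  class(cfg) <- "synth_config"
  cfg
}

#' Simulate an ultrametric birth-death chronogram
#'
#' Birth-death tree conditioned on the tip count, rescaled to the
#' configured crown age. Byte-identical under a fixed config.
#'
#' @param config A [synth_config()].
#' @return A `chronogram` with `n_tips` tips labelled `g001, g002, ...`.
#' @export
simulate_chronogram <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  if (config$death >= config$birth && config$birth > 0)
    stop("cannot condition on tip count with death >= birth")
  set.seed(config$seed)
  tree <- ape::rphylo(config$n_tips, birth = config$birth,
                      death = config$death)
  tree$tip.label <- sprintf("g%03d", seq_len(config$n_tips))
  depth <- max(node_depths(tree))
  tree$edge.length <- tree$edge.length * config$crown_age / depth
  as_chronogram(tree)
}

#' Simulate a thermal preference trait under lambda-scaled Brownian motion
#'
#' Multivariate-normal draw around the root state with covariance
#' `sigma2 *` [lambda_transform()] of the tree.
#'
#' @param tree A `chronogram`/`phylo` object.
#' @param config A [synth_config()].
#' @return Named numeric vector genus -> preference (deg C).
#' @export
simulate_trait <- function(tree, config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed + 1L)
  n <- ape::Ntip(tree)
  if (config$trait_sigma2 == 0)
    return(stats::setNames(rep(config$trait_root, n), tree$tip.label))
  V <- config$trait_sigma2 * lambda_transform(tree, config$trait_lambda)
  x <- config$trait_root + as.numeric(t(chol(V)) %*% stats::rnorm(n))
  stats::setNames(x, tree$tip.label)
}

#' Simulate extant species richness per genus
#'
#' Deterministic regime inverting the stem-age rate estimator:
#' `n = round(exp(r(T) * t))` with `r(T) = max(0, a + b * T)`, the
#' exponent capped at `log(1e6)`. With `b > 0`, warm-adapted genera are
#' species-rich, encoding a temperature-increasing diversification regime
#' that downstream regressions should recover.
#'
#' @param stem_ages Named numeric vector genus -> stem age (Ma).
#' @param trait Named numeric vector genus -> thermal preference (deg C).
#' @param config A [synth_config()].
#' @return Named integer vector genus -> species count (>= 1).
#' @export
simulate_richness <- function(stem_ages, trait, config) {
  stopifnot(inherits(config, "synth_config"))
  genus <- names(stem_ages)
  r <- pmax(0, config$rich_a + config$rich_b * trait[genus])
  expo <- pmin(r * stem_ages, log(1e6))
  stats::setNames(pmax(1L, as.integer(round(exp(expo)))), genus)
}

#' Life-form assignment from thermal preference
#'
#' @param trait Named numeric vector genus -> preference.
#' @param config A [synth_config()].
#' @return Named character vector in `{epiphyte, non_epiphyte}`.
#' @export
assign_life_form <- function(trait, config) {
  thr <- stats::quantile(trait, config$epiphyte_quantile)
  stats::setNames(ifelse(trait > thr, "epiphyte", "non_epiphyte"),
                  names(trait))
}

#' Simulate gradient occurrence records and climate calibration points
#'
#' Each gradient gets a seeded sea-level temperature and elevational bands
#' at midpoints `band_width/2, 3*band_width/2, ...` up to `max_elevation`.
#' Band temperature follows the linear lapse; a genus occupies a band
#' exactly when the band temperature lies within `preference +/-
#' niche_breadth` (optionally thinned by `dropout`). Calibration points
#' are emitted for Bio1/Bio5/Bio6 (linear lapse, fixed offsets +8/-9 deg C
#' for Bio5/Bio6) and Bio12 (a quadratic precipitation surface peaking at
#' mid-elevation), with configurable noise.
#'
#' @param tree A `chronogram`/`phylo` object (tips = genera).
#' @param trait Named numeric vector genus -> thermal preference.
#' @param config A [synth_config()].
#' @return List with `records` (band record data frame), `climate_points`
#'   (calibration data frame), `life_form` (named vector), and
#'   `gradient_base_temp` (named vector of seeded sea-level temperatures).
#' @export
simulate_records <- function(tree, trait, config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed + 2L)
  genera <- tree$tip.label
  life_form <- assign_life_form(trait, config)
  bands <- seq(config$band_width / 2, config$max_elevation,
               by = config$band_width)
  base <- config$base_temp +
    stats::runif(config$n_gradients, -config$base_temp_spread,
                 config$base_temp_spread)
  names(base) <- sprintf("G%d", seq_len(config$n_gradients))

  recs <- list(); clim <- list()
  for (gi in seq_len(config$n_gradients)) {
    gid <- names(base)[gi]
    band_temp <- base[gi] - config$lapse * bands / 1000
    occ <- outer(trait[genera], band_temp,
                 function(p, tt) abs(p - tt) <= config$niche_breadth)
    idx <- which(occ, arr.ind = TRUE)
    if (nrow(idx)) {
      df <- data.frame(
        gradient_id = gid,
        genus = genera[idx[, 1L]],
        elevation_m = bands[idx[, 2L]],
        class = "all",
        stringsAsFactors = FALSE
      )
      if (config$dropout > 0)
        df <- df[stats::runif(nrow(df)) >= config$dropout, , drop = FALSE]
      if (config$life_form_classes && nrow(df)) {
        lf <- df
        lf$class <- ifelse(life_form[lf$genus] == "epiphyte",
                           "epiphyte", "non_epiphyte")
        df <- rbind(df, lf)
      }
      recs[[gid]] <- df
    }
    prec <- 1500 + 1.0 * bands - 0.00025 * bands^2
    clim[[gid]] <- data.frame(
      gradient_id = gid,
      variable = rep(c("bio1", "bio5", "bio6", "bio12"),
                     each = length(bands)),
      elevation_m = rep(bands, 4L),
      value = c(band_temp + stats::rnorm(length(bands), 0, config$climate_noise_temp),
                band_temp + 8 + stats::rnorm(length(bands), 0, config$climate_noise_temp),
                band_temp - 9 + stats::rnorm(length(bands), 0, config$climate_noise_temp),
                prec + stats::rnorm(length(bands), 0, config$climate_noise_prec)),
      stringsAsFactors = FALSE
    )
  }
  records <- do.call(rbind, c(recs, list(make.row.names = FALSE)))
  if (is.null(records) || nrow(records) == 0L)
    records <- data.frame(gradient_id = character(0), genus = character(0),
                          elevation_m = numeric(0), class = character(0),
                          stringsAsFactors = FALSE)
  list(records = records,
       climate_points = do.call(rbind, c(clim, list(make.row.names = FALSE))),
       life_form = life_form,
       gradient_base_temp = base)
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper chaining [simulate_chronogram()],
#' [simulate_trait()], [simulate_richness()] and [simulate_records()] into
#' the full input bundle every downstream stage consumes.
#'
#' @param config A [synth_config()].
#' @return List with `tree`, `trait`, `genus_table` (genus, species_count,
#'   life_form, family), `records`, `climate_points`,
#'   `gradient_base_temp`, and the `config`.
#' @export
synth_dataset <- function(config = synth_config()) {
  tree <- simulate_chronogram(config)
  trait <- simulate_trait(tree, config)
  ages <- stem_age(tree)
  counts <- simulate_richness(ages, trait, config)
  rec <- simulate_records(tree, trait, config)
  genus_table <- data.frame(
    genus = tree$tip.label,
    species_count = as.integer(counts[tree$tip.label]),
    life_form = unname(rec$life_form[tree$tip.label]),
    family = NA_character_,
    stringsAsFactors = FALSE
  )
  list(tree = tree, trait = trait, genus_table = genus_table,
       records = rec$records, climate_points = rec$climate_points,
       gradient_base_temp = rec$gradient_base_temp, config = config)
}
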