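#' Default calibration targets for the synthetic wage-earner sample
#'
#' The package ships a fixed calibration describing a six-class
#' employment-quality (EQ) typology among U.S. wage earners, modelled on the
#' pooled General Social Survey Quality of Work Life waves (2002, 2006, 2010,
#' 2014, 2018): gender-specific class-membership distributions, class- and
#' gender-specific probabilities of the two binary health outcomes (poor
#' self-rated health and frequent mental distress), confounder margins, and
#' the sample-size / missingness profile of the analytic sample.  These
#' quantities drive [default_config()] and serve as the worked example for
#' [decompose_from_probabilities()].
#'
#' @return A list with components:
#' \describe{
#'   \item{class_labels}{character vector of the six EQ type labels, the
#'     first ("SER-like") being the reference class.}
#'   \item{class_dist}{6 x 2 matrix of class-membership probabilities with
#'     columns `woman` and `man`; each column sums to 1.}
#'   \item{outcome_probs}{list with elements `srh_poor` and `fmd`, each a
#'     6 x 2 matrix of P(outcome = 1 | gender, class).}
#'   \item{confounder_marginals}{list of category probabilities for age band,
#'     race/ethnicity, nativity and survey wave.}
#'   \item{sample}{list of sample-size constants: initial n, analytic n,
#'     number of women, and the missingness counts (too few EQ indicators,
#'     missing age, missing each outcome).}
#' }
#' @export
#' @examples
#' cal <- default_calibration()
#' colSums(cal$class_dist)
default_calibration <- function() {
  labels <- c("SER-like", "Portfolio", "Inflexible skilled", "Dead-end",
              "Precarious", "Optimistic precarious")
  class_dist <- cbind(
    woman = c(0.285, 0.046, 0.116, 0.080, 0.215, 0.258),
    man   = c(0.201, 0.175, 0.233, 0.136, 0.106, 0.149)
  )
  rownames(class_dist) <- labels
  srh <- cbind(
    woman = c(0.073, 0.014, 0.073, 0.111, 0.160, 0.078),
    man   = c(0.076, 0.030, 0.055, 0.153, 0.149, 0.176)
  )
  fmd <- cbind(
    woman = c(0.107, 0.081, 0.126, 0.206, 0.329, 0.170),
    man   = c(0.044, 0.094, 0.167, 0.240, 0.219, 0.136)
  )
  rownames(srh) <- rownames(fmd) <- labels
  list(
    class_labels = labels,
    class_dist = class_dist,
    outcome_probs = list(srh_poor = srh, fmd = fmd),
    confounder_marginals = list(
      age_band = c("<30" = 1521, "30-50" = 3077, ">50" = 1769) / 6367,
      race_eth = c(white = 4339, black = 1004, hispanic = 747,
                   asian_pi = 202, aian = 75) / 6367,
      nativity = c(us_born = 5629, foreign_born = 738) / 6367,
      wave = c("2002" = 1542, "2006" = 1489, "2010" = 1011,
               "2014" = 1068, "2018" = 1257) / 6367
    ),
    sample = list(
      n_initial = 6421L,
      n_analytic = 6367L,
      n_women = 3405L,
      prop_women = 3405 / 6367,
      missing = list(indicators = 32L, age = 22L, srh_poor = 32L, fmd = 71L)
    )
  )
}

# Fixed category level sets used throughout the package.
GENDER_LEVELS   <- c("man", "woman")
AGE_LEVELS      <- c("<30", "30-50", ">50")
RACE_LEVELS     <- c("white", "black", "hispanic", "asian_pi", "aian")
NATIVITY_LEVELS <- c("us_born", "foreign_born")
WAVE_LEVELS     <- c("2002", "2006", "2010", "2014", "2018")

# Reference levels: man; age 30-50; white; US-born; wave 2002.
CONF_DUMMY_NAMES <- c("age_lt30", "age_gt50",
                      "race_black", "race_hispanic", "race_asian_pi",
                      "race_aian", "nativity_foreign",
                      "wave_2006", "wave_2010", "wave_2014", "wave_2018")
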