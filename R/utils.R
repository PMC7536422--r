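# Logging, configuration, small shared helpers.

#' Emit a log line to stderr
#'
#' Levels: DEBUG < INFO < WARN.  The threshold is the option
#' `hybridzone.verbosity` ("DEBUG", "INFO", "WARN", or "SILENT"; default
#' "INFO").  Every stochastic operation in the package logs its seed through
#' this channel.
#'
#' @param level one of "DEBUG", "INFO", "WARN"
#' @param ... pieces pasted into the message
#' @return invisibly, the message text
#' @export
hz_log <- function(level = "INFO", ...) {
  lv <- c(DEBUG = 1L, INFO = 2L, WARN = 3L)
  thr <- getOption("hybridzone.verbosity", "INFO")
  if (identical(thr, "SILENT")) return(invisible(NULL))
  msg <- paste0("[", level, "] ", paste0(..., collapse = ""))
  if (lv[[level]] >= lv[[thr]]) message(msg)
  invisible(msg)
}

#' Default analysis configuration
#'
#' Central registry of tunable settings: the population-label vocabulary,
#' prior bounds for the demographic parameters, mutation-model defaults,
#' admixture-chain settings, and morphometric choices.  Everything the
#' simulators and estimators treat as a constant lives here so a structured
#' config file can override it.
#'
#' @return a named nested list
#' @export
default_config <- function() {
  list(
    populations = c("AlpineCarpathian", "NEEuropean", "Asian"),
    loci = c("Mon_08", "Mon_17", "Mon_30", "Mon_31", "Mon_36", "Mon_44"),
    mutation = list(
      mu_ssr = 5e-4, p_gsm = 0.2, range = 40,
      mu_site = 5.74e-8, seq_length = 658
    ),
    priors_ssr = list(
      params = list(
        N1  = list(dist = "unif",    min = 100, max = 3e5),
        N2  = list(dist = "unif",    min = 100, max = 3e5),
        N3  = list(dist = "unif",    min = 100, max = 3e5),
        NA_ = list(dist = "unif",    min = 100, max = 3e5),
        t1  = list(dist = "unif",    min = 100, max = 3e5),
        t2  = list(dist = "unif",    min = 100, max = 3e5),
        r   = list(dist = "unif",    min = 0.001, max = 0.999),
        mu_ssr = list(dist = "logunif", min = 1e-4, max = 1e-3),
        p_gsm  = list(dist = "unif",    min = 0.1, max = 0.3)
      ),
      conditions = list(c("t2", "t1"))   # t2 < t1
    ),
    priors_mtdna = list(
      params = list(
        N1  = list(dist = "unif",    min = 100, max = 3e5),
        N2  = list(dist = "unif",    min = 100, max = 3e5),
        NA_ = list(dist = "unif",    min = 100, max = 3e5),
        ta  = list(dist = "unif",    min = 100, max = 3e5),
        mu_site = list(dist = "logunif", min = 1e-8, max = 1e-7)
      ),
      conditions = list()
    ),
    ancestry = list(burn_in = 10000, length = 50000, n_rep = 10,
                    k_range = 1:5, alpha_step = 0.05, alpha_max = 10),
    abc = list(keep_fraction = 0.01),
    morpho = list(n_pcs = 20, rarefaction_genes = 44)
  )
}

#' Read a configuration file
#'
#' Reads a YAML config and merges it over [default_config()]: keys present in
#' the file replace the defaults, everything else is kept.
#'
#' @param path YAML file path
#' @return a config list
#' @export
read_config <- function(path) {
  usr <- yaml::read_yaml(path)
  merge_config(default_config(), usr)
}

merge_config <- function(base, usr) {
  for (k in names(usr)) {
    if (is.list(usr[[k]]) && is.list(base[[k]]) && !is.null(base[[k]])) {
      base[[k]] <- merge_config(base[[k]], usr[[k]])
    } else {
      base[[k]] <- usr[[k]]
    }
  }
  base
}

#' Write a configuration file
#' @param config a config list
#' @param path output YAML path
#' @return `path`, invisibly
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

# seed handling: set the RNG when a seed is given and log it
with_seed_logged <- function(seed, what) {
  if (!is.null(seed)) {
    set.seed(as.integer(seed))
    hz_log("DEBUG", what, ": seed = ", seed)
  }
  invisible(seed)
}

# derive a reproducible sub-seed (< 2^31) from a master seed and a tag
derive_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 7919 + offset * 104729) %% 2147483587) + 1L
}

trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

weighted_quantile <- function(x, w, probs) {
  ord <- order(x)
  x <- x[ord]; w <- w[ord] / sum(w)
  cw <- cumsum(w)
  vapply(probs, function(p) x[which(cw >= p)[1]], numeric(1))
}
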