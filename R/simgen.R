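# Coalescent simulator of microsatellite genotypes and mtDNA sequences under
# divergence + admixture demographic scenarios, plus an F-model genotype
# generator with per-individual known ancestry.  The coalescent is the
# standard n-coalescent with exponential waiting times; splits merge lineage
# sets, an admixture event routes each target lineage to one of two sources,
# and population sizes may change at events.  Microsatellite mutation follows
# the generalised stepwise model (geometric step sizes, reflecting bounds);
# mtDNA uses Jukes-Cantor substitutions.

#' Define a demographic scenario
#'
#' Populations are ordered, with effective sizes in *individuals* (diploid
#' for nuclear microsatellites, haploid females for mtDNA).  Events, ordered
#' by time into the past: `split(time, from, to)` moves all lineages of
#' `from` into `to`; `admix(time, target, source_a, source_b, r)` sends each
#' `target` lineage to `source_a` with probability `r`, else to `source_b`;
#' `resize(time, pop, size)` changes a population's effective size.
#'
#' @param populations character vector of population labels
#' @param sizes effective sizes, one per population
#' @param events a data frame with columns `time`, `type`
#'   ("split"/"admix"/"resize"), `a`, `b`, `c`, `r` (populations by label or
#'   index; unused fields NA)
#' @param name scenario name
#' @return a `demog_scenario` object
#' @export
demographic_scenario <- function(populations, sizes, events, name = "scenario") {
  stopifnot(length(populations) == length(sizes), all(sizes > 0))
  ev <- as_tibble(events)
  for (col in c("a", "b", "c")) {
    if (is.character(ev[[col]])) ev[[col]] <- match(ev[[col]], populations)
  }
  if (is.unsorted(ev$time)) stop("event times must be non-decreasing into the past")
  if (any(ev$type == "admix" & (ev$r < 0 | ev$r > 1), na.rm = TRUE))
    stop("admixture proportion r must lie in [0, 1]")
  scn <- structure(list(populations = populations, sizes = sizes,
                        events = ev, name = name),
                   class = "demog_scenario")
  validate_scenario(scn)
  scn
}

# every population must ultimately merge into a single lineage pool
validate_scenario <- function(scn) {
  alive <- rep(TRUE, length(scn$populations))
  for (i in seq_len(nrow(scn$events))) {
    ev <- scn$events[i, ]
    if (ev$type %in% c("split", "admix")) alive[ev$a] <- FALSE
  }
  if (sum(alive) != 1)
    stop("scenario invalid: exactly one lineage pool must remain after the oldest event")
  invisible(scn)
}

#' @export
print.demog_scenario <- function(x, ...) {
  cat("Demographic scenario:", x$name, "\n")
  cat("  populations:", paste0(x$populations, " (N=", signif(x$sizes, 4), ")",
                               collapse = ", "), "\n")
  cat("  events:\n")
  print(as.data.frame(x$events))
  invisible(x)
}

#' Define a mutation model
#'
#' @param mu_ssr microsatellite mutation rate per locus per generation
#' @param p_gsm geometric parameter of the generalised stepwise model
#'   (0 = strict single-step), in `[0, 1)`
#' @param range number of contiguous allowed allele states (reflecting bounds)
#' @param mu_site mtDNA substitution rate per site per generation
#' @param seq_length mtDNA sequence length (bp)
#' @return a `mutation_model` list
#' @export
mutation_model <- function(mu_ssr = 5e-4, p_gsm = 0.2, range = 40,
                           mu_site = 5.74e-8, seq_length = 658) {
  stopifnot(mu_ssr > 0 || mu_site >= 0, p_gsm >= 0, p_gsm < 1, range >= 2)
  structure(list(mu_ssr = mu_ssr, p_gsm = p_gsm, range = range,
                 mu_site = mu_site, seq_length = seq_length),
            class = "mutation_model")
}

# convert a scenario to the event matrix the C++ kernel consumes;
# `scale` = 2 for diploid nuclear loci, 1 for mtDNA
scenario_events_matrix <- function(scn, scale = 2) {
  ev <- scn$events
  m <- matrix(0, nrow(ev), 6)
  for (i in seq_len(nrow(ev))) {
    m[i, 1] <- ev$time[i]
    m[i, 3] <- ev$a[i]
    if (ev$type[i] == "split") {
      m[i, 2] <- 0; m[i, 4] <- ev$b[i]
    } else if (ev$type[i] == "admix") {
      m[i, 2] <- 1; m[i, 4] <- ev$b[i]; m[i, 5] <- ev$c[i]; m[i, 6] <- ev$r[i]
    } else if (ev$type[i] == "resize") {
      m[i, 2] <- 2; m[i, 6] <- scale * ev$r[i]
    } else stop("unknown event type: ", ev$type[i])
  }
  m
}

#' Simulate microsatellite genotypes under a demographic scenario
#'
#' One independent coalescent tree per locus; mutations are Poisson on
#' branches with geometric signed step sizes reflected at the range bounds;
#' diploid genotypes pair consecutive gene copies (exchangeable under the
#' coalescent).  Allele states are reported as fragment sizes offset by 100.
#'
#' @param scn a `demog_scenario`
#' @param mut a `mutation_model`
#' @param sample_sizes diploid individuals sampled per population (named or
#'   in population order; 0 allowed)
#' @param n_loci number of loci
#' @param seed RNG seed
#' @param loci optional locus names
#' @return a `geno_tbl`
#' @export
simulate_ssr <- function(scn, mut, sample_sizes, n_loci = 6, seed = NULL,
                         loci = NULL) {
  with_seed_logged(seed, "simulate_ssr")
  pops <- scn$populations
  ns <- normalize_sample_sizes(sample_sizes, pops)
  loci <- loci %||% paste0("L", seq_len(n_loci))
  ev <- scenario_events_matrix(scn, scale = 2)
  popsize <- 2 * scn$sizes
  ncopies <- 2L * ns
  ids <- unlist(lapply(seq_along(pops), function(p)
    if (ns[p] > 0) paste0(substr(pops[p], 1, 3), "_", seq_len(ns[p])) else character(0)))
  popv <- rep(pops, ns)
  n <- length(ids)
  A1 <- matrix(0L, n, n_loci); A2 <- matrix(0L, n, n_loci)
  for (l in seq_len(n_loci)) {
    tr <- cpp_coal_tree(ncopies, popsize, ev)
    st <- cpp_mutate_gsm(tr$parent, tr$time, tr$n_tips, mut$mu_ssr,
                         mut$p_gsm, mut$range) + 100L
    a1 <- st[seq(1, length(st), by = 2)]
    a2 <- st[seq(2, length(st), by = 2)]
    A1[, l] <- pmin(a1, a2); A2[, l] <- pmax(a1, a2)
  }
  out <- tibble::new_tibble(list(
    id = rep(ids, each = n_loci), pop = rep(popv, each = n_loci),
    locus = rep(loci, n), a1 = as.integer(t(A1)), a2 = as.integer(t(A2))),
    nrow = n * n_loci)
  attr(out, "loci") <- loci
  attr(out, "pops") <- pops[ns > 0]
  class(out) <- c("geno_tbl", class(out))
  out
}

#' Simulate mtDNA haplotype sequences under a demographic scenario
#'
#' Single-locus coalescent with Jukes-Cantor substitutions (Poisson on
#' branches, uniform sites).  Population sizes are interpreted as haploid
#' (female) effective sizes.
#'
#' @param scn a `demog_scenario`
#' @param mut a `mutation_model` (uses `mu_site`, `seq_length`)
#' @param sample_sizes haploid sequences sampled per population
#' @param seed RNG seed
#' @return a `seq_tbl`
#' @export
simulate_mtdna <- function(scn, mut, sample_sizes, seed = NULL) {
  with_seed_logged(seed, "simulate_mtdna")
  pops <- scn$populations
  ns <- normalize_sample_sizes(sample_sizes, pops)
  ev <- scenario_events_matrix(scn, scale = 1)
  tr <- cpp_coal_tree(ns, scn$sizes, ev)
  m <- cpp_mutate_jc69(tr$parent, tr$time, tr$n_tips, mut$mu_site, mut$seq_length)
  bases <- c("A", "C", "G", "T")
  seqs <- apply(m, 1, function(row) paste0(bases[row + 1], collapse = ""))
  ids <- unlist(lapply(seq_along(pops), function(p)
    if (ns[p] > 0) paste0(substr(pops[p], 1, 3), "_h", seq_len(ns[p])) else character(0)))
  sequence_tbl(tibble(id = ids, pop = rep(pops, ns), seq = seqs))
}

normalize_sample_sizes <- function(sample_sizes, pops) {
  if (!is.null(names(sample_sizes))) {
    ns <- integer(length(pops))
    ns[match(names(sample_sizes), pops)] <- as.integer(sample_sizes)
  } else {
    ns <- as.integer(sample_sizes)
    length(ns) <- length(pops)
    ns[is.na(ns)] <- 0L
  }
  if (any(ns < 0)) stop("sample sizes must be >= 0")
  ns
}

#' Built-in demographic scenario catalogue
#'
#' Nuclear-microsatellite family (three sampled populations
#' AlpineCarpathian / NEEuropean / Asian): scenario 2 is the
#' secondary-contact hypothesis — the northeastern European population is
#' founded at `t2` as an admixture of the Alpine-Carpathian (proportion `r`)
#' and Asian (1 - r) lineages, which merge into the ancestor at `t1`.
#' Scenarios 1, 3, 4 are the pure-bifurcation alternatives
#' ((NE,Asia),AC), ((NE,AC),Asia) and a simultaneous trichotomy.
#'
#' mtDNA family (two sampled populations, divergence at `ta` from an
#' ancestor of size `NA_`): five constraint variants on (N1, N2, NA_):
#' 1 all free; 2 N1 = NA_; 3 N1 = N2; 4 all equal; 5 N2 = NA_.
#'
#' Each entry is a builder: a function of a named parameter vector
#' (N1, N2, N3, NA_, t1, t2, r for SSR; N1, N2, NA_, ta for mtDNA)
#' returning a `demog_scenario`.
#'
#' @param type "ssr" or "mtdna"
#' @param populations population labels (defaults from [default_config()])
#' @return a named list of builder functions
#' @export
scenario_catalogue <- function(type = c("ssr", "mtdna"), populations = NULL) {
  type <- match.arg(type)
  cfg <- default_config()
  if (type == "ssr") {
    pops <- populations %||% cfg$populations  # AC, NE, Asian
    mk <- function(build_events) {
      function(par) {
        par <- as.list(par)
        demographic_scenario(pops,
                             sizes = c(par$N1, par$N2, par$N3),
                             events = build_events(par))
      }
    }
    list(
      # ((NE, Asia), AC): NE joins Asia at t2, Asia joins AC at t1
      scenario1 = mk(function(p) tibble(
        time = c(p$t2, p$t1, p$t1),
        type = c("split", "split", "resize"),
        a = c(2, 3, 1), b = c(3, 1, NA), c = NA, r = c(NA, NA, p$NA_))),
      # secondary contact: NE founded at t2 by admixture AC (r) x Asia (1-r)
      scenario2 = mk(function(p) tibble(
        time = c(p$t2, p$t1, p$t1),
        type = c("admix", "split", "resize"),
        a = c(2, 3, 1), b = c(1, 1, NA), c = c(3, NA, NA),
        r = c(p$r, NA, p$NA_))),
      # ((NE, AC), Asia): NE joins AC at t2, AC joins Asia at t1
      scenario3 = mk(function(p) tibble(
        time = c(p$t2, p$t1, p$t1),
        type = c("split", "split", "resize"),
        a = c(2, 1, 3), b = c(1, 3, NA), c = NA, r = c(NA, NA, p$NA_))),
      # simultaneous trichotomy at t1
      scenario4 = mk(function(p) tibble(
        time = c(p$t1, p$t1, p$t1),
        type = c("split", "split", "resize"),
        a = c(2, 3, 1), b = c(1, 1, NA), c = NA, r = c(NA, NA, p$NA_)))
    )
  } else {
    pops <- populations %||% c("Asian", "AlpineCarpathian")
    mkm <- function(constrain) {
      function(par) {
        par <- constrain(as.list(par))
        demographic_scenario(pops, sizes = c(par$N1, par$N2),
                             events = tibble(
                               time = c(par$ta, par$ta),
                               type = c("split", "resize"),
                               a = c(2, 1), b = c(1, NA), c = NA,
                               r = c(NA, par$NA_)))
      }
    }
    list(
      scenario1 = mkm(function(p) p),                          # all free
      scenario2 = mkm(function(p) { p$N1 <- p$NA_; p }),       # N1 = NA
      scenario3 = mkm(function(p) { p$N2 <- p$N1; p }),        # N1 = N2
      scenario4 = mkm(function(p) { p$N1 <- p$NA_; p$N2 <- p$NA_; p }),
      scenario5 = mkm(function(p) { p$N2 <- p$NA_; p })        # N2 = NA
    )
  }
}

#' Draw parameter vectors from a prior specification
#'
#' Independent draws per parameter (uniform or log-uniform), then rejection
#' until every conditioning rule (pairs `c(smaller, larger)`) holds.
#'
#' @param priors list with `params` (per parameter: `dist`, `min`, `max`) and
#'   `conditions` (list of 2-vectors naming parameters, smaller first)
#' @param n number of draws
#' @param seed RNG seed
#' @return a tibble of parameter draws, one row per draw
#' @export
draw_prior <- function(priors, n = 1, seed = NULL) {
  with_seed_logged(seed, "draw_prior")
  ps <- priors$params
  for (p in ps) {
    stopifnot(is.finite(p$min), is.finite(p$max), p$min <= p$max)
  }
  draw_block <- function(m) {
    out <- lapply(ps, function(p) {
      if (p$dist == "unif") runif(m, p$min, p$max)
      else if (p$dist == "logunif") exp(runif(m, log(p$min), log(p$max)))
      else stop("unknown prior family: ", p$dist)
    })
    as_tibble(setNames(out, names(ps)))
  }
  ok_rows <- function(d) {
    keep <- rep(TRUE, nrow(d))
    for (cond in priors$conditions) keep <- keep & (d[[cond[1]]] < d[[cond[2]]])
    keep
  }
  out <- draw_block(n)
  keep <- ok_rows(out)
  tries <- 0L
  while (any(!keep)) {
    m <- sum(!keep)
    tries <- tries + 1L
    if (tries > 1000L) stop("degenerate prior: condition rejection rate > 99.9%")
    cand <- draw_block(max(m, 10L))
    cand <- cand[ok_rows(cand), , drop = FALSE]
    if (nrow(cand) > 0) {
      take <- min(nrow(cand), m)
      out[which(!keep)[seq_len(take)], ] <- cand[seq_len(take), ]
      keep <- ok_rows(out)
    }
  }
  out
}

#' Simulate admixed multilocus genotypes with known individual ancestry
#'
#' F-model generator: ancestral allele frequencies per locus are Dirichlet;
#' the two cluster frequency vectors are Dirichlet around them with
#' concentration `(1 - fst) / fst`, so the expected differentiation between
#' the clusters is approximately `fst`.  Each gene copy of individual `i`
#' originates from cluster 1 with probability `q[i]`.  Individuals flagged
#' `f1` receive exactly one gene copy from each cluster at every locus
#' (first-generation hybrids).
#'
#' @param q numeric vector of true cluster-1 ancestry proportions, one per
#'   individual
#' @param fst target differentiation between the two clusters
#' @param n_loci number of loci
#' @param n_alleles alleles per locus (single number or vector)
#' @param pop optional population labels per individual
#' @param f1 logical vector flagging F1 hybrids
#' @param seed RNG seed
#' @return a `geno_tbl` with attribute `true_q` (the input `q`)
#' @export
simulate_admixed_genotypes <- function(q, fst = 0.18, n_loci = 6,
                                       n_alleles = 8, pop = NULL,
                                       f1 = NULL, seed = NULL) {
  with_seed_logged(seed, "simulate_admixed_genotypes")
  n <- length(q)
  stopifnot(all(q >= 0 & q <= 1), fst > 0, fst < 1)
  f1 <- f1 %||% rep(FALSE, n)
  pop <- pop %||% rep("synthetic", n)
  n_alleles <- rep(n_alleles, length.out = n_loci)
  # the realized pairwise Weir-Cockerham theta between the two clusters
  # (each Dirichlet-drifted around the shared ancestor) is ~ fst itself
  lam <- (1 - fst) / fst
  ids <- sprintf("ind_%03d", seq_len(n))
  recs <- vector("list", n_loci)
  for (l in seq_len(n_loci)) {
    A <- n_alleles[l]
    pa <- rgamma(A, 1); pa <- pa / sum(pa)
    p1 <- rgamma(A, lam * pa); p1 <- p1 / sum(p1)
    p2 <- rgamma(A, lam * pa); p2 <- p2 / sum(p2)
    a1 <- integer(n); a2 <- integer(n)
    for (i in seq_len(n)) {
      if (f1[i]) {
        a1[i] <- sample.int(A, 1, prob = p1)
        a2[i] <- sample.int(A, 1, prob = p2)
      } else {
        src <- runif(2) < q[i]
        a1[i] <- sample.int(A, 1, prob = if (src[1]) p1 else p2)
        a2[i] <- sample.int(A, 1, prob = if (src[2]) p1 else p2)
      }
    }
    sw <- a1 > a2; tmp <- a1[sw]; a1[sw] <- a2[sw]; a2[sw] <- tmp
    recs[[l]] <- tibble(id = ids, pop = pop, locus = paste0("L", l),
                        a1 = a1 + 100L, a2 = a2 + 100L)
  }
  out <- genotype_tbl(arrange(bind_rows(recs), match(.data$id, ids)),
                      loci = paste0("L", seq_len(n_loci)),
                      pops = unique(pop))
  attr(out, "true_q") <- q
  out
}
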