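#' Exact-count copy-number profile
#'
#' Point mass at a known integer copy number, the representation for
#' counts read directly from assembled genomes (unlike a qPCR estimate,
#' zero is a legitimate observed value).
#'
#' @param count Observed copy number (integer >= 0).
#' @param n_max Largest state.
#' @return A `copy_profile` with `obs_type = "count"`.
#' @export
count_profile <- function(count, n_max) {
  stopifnot(count >= 0, count == round(count))
  if (count > n_max) stop("count exceeds n_max")
  w <- numeric(n_max + 1)
  w[count + 1L] <- 1
  copy_profile(w, "count")
}

#' Simulate the chain over one branch for an ensemble of replicates
#'
#' Exact Gillespie simulation of the (uncapped) birth-death-innovation
#' process: at copy number `k >= 1` births occur at rate `b * k` and
#' deletions at `d * k`; at `k = 0` only innovation (rate `i`) can occur.
#' All replicates are advanced together, so large ensembles (the package's
#' central simulator-vs-matrix-exponential cross-check) run in vectorized
#' R.
#'
#' @param k0 Integer vector of start states (one per replicate).
#' @param rates A `rate_spec` or list with `b`, `d`, `i`.
#' @param t Branch length (>= 0).
#' @return List with integer vectors `state`, `births`, `deletions`,
#'   `innovations`, each of length `length(k0)`.
#' @export
simulate_branch <- function(k0, rates, t) {
  stopifnot(all(k0 >= 0), t >= 0)
  b <- rates$b; d <- rates$d; i <- rates$i
  n <- length(k0)
  k <- as.numeric(k0)
  tm <- numeric(n)
  nb <- nd <- ni <- integer(n)
  active <- seq_len(n)
  while (length(active)) {
    rate <- ifelse(k[active] == 0, i, (b + d) * k[active])
    live <- rate > 0
    active <- active[live]; rate <- rate[live]
    if (!length(active)) break
    tm[active] <- tm[active] + rexp(length(active), rate)
    hit <- tm[active] <= t
    ev <- active[hit]
    active <- ev
    if (!length(ev)) break
    zero <- k[ev] == 0
    if (any(zero)) {
      z <- ev[zero]
      k[z] <- 1; ni[z] <- ni[z] + 1L
    }
    pos <- ev[!zero]
    if (length(pos)) {
      birth <- runif(length(pos)) < b / (b + d)
      up <- pos[birth]; down <- pos[!birth]
      k[up] <- k[up] + 1; nb[up] <- nb[up] + 1L
      k[down] <- k[down] - 1; nd[down] <- nd[down] + 1L
    }
  }
  list(state = as.integer(k), births = nb, deletions = nd, innovations = ni)
}

#' Simulate one gene family along the tree
#'
#' Runs the Gillespie process down every branch, using the branch class's
#' rates, and records the per-branch event log.  The simulation itself is
#' uncapped; callers that need a truncated state space cap on output.
#'
#' @param tree A `"phylo"` object.
#' @param classes Branch class map.
#' @param rates_by_class Named list: class -> `rate_spec`.
#' @param root_state Copy number at the root (integer >= 0).
#' @param seed Optional integer seed (`set.seed` is called when given;
#'   pass `NULL` to draw from the current stream).
#' @return List with `tip_states` (named integer vector over leaves),
#'   `node_states` (all nodes), and `events` (data frame: branch child
#'   node, class, births, deletions, innovations).
#' @export
simulate_family <- function(tree, classes, rates_by_class, root_state,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (root_state < 0 || root_state != round(root_state)) {
    stop("invalid root state")
  }
  tv <- tree_traversal(tree, classes)
  states <- integer(tv$nnode)
  states[tv$root] <- as.integer(root_state)
  ne <- nrow(tv$edge)
  ev <- data.frame(branch = tv$edge[, 2], class = tv$edge.class,
                   births = integer(ne), deletions = integer(ne),
                   innovations = integer(ne))
  for (e in rev(seq_len(ne))) {   # reverse postorder = preorder over edges
    par <- tv$edge[e, 1]; child <- tv$edge[e, 2]
    r <- rates_by_class[[tv$edge.class[e]]] %||% rates_by_class[["all"]]
    if (is.null(r)) stop("no rates for class: ", tv$edge.class[e])
    s <- simulate_branch(states[par], r, tv$edge.length[e])
    states[child] <- s$state
    ev$births[e] <- s$births; ev$deletions[e] <- s$deletions
    ev$innovations[e] <- s$innovations
  }
  tips <- setNames(states[seq_len(tv$ntip)], tv$tree$tip.label)
  list(tip_states = tips, node_states = states, events = ev)
}

## Deterministic per-family substream: family order or count never changes
## another family's draws.
family_substream_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + index * 16807) %% 2147483647)
}

#' Simulate a full dataset of independent gene families
#'
#' @param tree A `"phylo"` object.
#' @param classes Branch class map.
#' @param config A list with one element per category to simulate; each
#'   element is a list with `n` (family count), `rates` (named list:
#'   class -> `rate_spec`), and `root_state`.
#' @param seed Integer seed; each family gets its own deterministic
#'   substream derived from it, so results are invariant to the order and
#'   number of other families.
#' @return A `sim_dataset`: list with `truth` (data frame: family,
#'   category, taxon, count), `tip_states` (family x taxon matrix),
#'   `events` (per family, per branch event counts), `seed`, `config`.
#' @export
simulate_dataset <- function(tree, classes, config, seed) {
  stopifnot(length(config) >= 1)
  fams <- character(0); cats <- character(0)
  tipm <- NULL; evs <- list()
  idx <- 0L
  for (cat in names(config)) {
    cc <- config[[cat]]
    if (is.null(cc$n) || cc$n < 0) stop("invalid family count for ", cat)
    if (cc$n == 0) next
    for (j in seq_len(cc$n)) {
      idx <- idx + 1L
      fid <- sprintf("%s_%04d", cat, j)
      sim <- simulate_family(tree, classes, cc$rates, cc$root_state,
                             seed = family_substream_seed(seed, idx))
      fams <- c(fams, fid); cats <- c(cats, cat)
      tipm <- rbind(tipm, sim$tip_states)
      evs[[fid]] <- sim$events
    }
  }
  rownames(tipm) <- fams
  truth <- data.frame(
    family = rep(fams, each = ncol(tipm)),
    category = rep(cats, each = ncol(tipm)),
    taxon = rep(colnames(tipm), times = length(fams)),
    count = as.integer(t(tipm)))
  structure(list(truth = truth, tip_states = tipm,
                 events = evs, category = setNames(cats, fams),
                 seed = seed, config = config),
            class = "sim_dataset")
}

#' Emulate the study's observation process on simulated truth
#'
#' Converts true tip counts into an observation table of the shape the
#' inference consumes.  Per category, an observation mode decides the row
#' type: `"qpcr"` draws a mean from Normal(truth, SE) truncated at > 0
#' (redrawn; a true count of 0 cannot amplify and is emitted as missing,
#' i.e. a failed assay), `"sequence-count"` reports
#' Binomial(truth, p_detect) unique sequences, and `"count"` reports the
#' exact count.  Masked (category, taxon) cells are emitted as missing
#' with no numeric fields.
#'
#' @param sim A `sim_dataset` from [simulate_dataset()].
#' @param modes Named character vector: category -> observation mode.
#' @param qpcr_se Either a single SE, or a range `c(lo, hi)` from which
#'   each (family, taxon) assay SE is drawn uniformly.
#' @param mask A list of masks, each a list with `categories` and `taxa`:
#'   all cells in their product are missing.
#' @param p_detect Per-copy detection probability for sequence-count
#'   rows.
#' @param seed Integer seed for the observation noise.
#' @return Data frame with columns `family`, `category`, `taxon`,
#'   `obs_type`, `mean`, `se`, `n_unique` (`NA` where not applicable).
#' @export
emulate_observations <- function(sim, modes, qpcr_se = c(0.05, 0.5),
                                 mask = list(), p_detect = 1, seed = 1) {
  set.seed(seed)
  tr <- sim$truth
  masked <- rep(FALSE, nrow(tr))
  for (m in mask) {
    masked <- masked | (tr$category %in% m$categories & tr$taxon %in% m$taxa)
  }
  obs_type <- character(nrow(tr))
  mean_v <- se_v <- rep(NA_real_, nrow(tr))
  uniq_v <- rep(NA_integer_, nrow(tr))
  for (r in seq_len(nrow(tr))) {
    if (masked[r]) { obs_type[r] <- "missing"; next }
    mode <- modes[[tr$category[r]]]
    if (is.null(mode)) stop("no observation mode for ", tr$category[r])
    k <- tr$count[r]
    if (mode == "qpcr") {
      if (k == 0) { obs_type[r] <- "missing"; next }  # failed assay
      se <- if (length(qpcr_se) == 2L) runif(1, qpcr_se[1], qpcr_se[2])
            else qpcr_se
      m <- rnorm(1, k, se)
      while (m <= 0) m <- rnorm(1, k, se)
      obs_type[r] <- "qpcr"; mean_v[r] <- m; se_v[r] <- se
    } else if (mode == "sequence-count") {
      obs_type[r] <- "sequence-count"
      uniq_v[r] <- rbinom(1, k, p_detect)
    } else if (mode == "count") {
      obs_type[r] <- "count"; mean_v[r] <- k
    } else stop("unknown observation mode: ", mode)
  }
  data.frame(family = tr$family, category = tr$category, taxon = tr$taxon,
             obs_type = obs_type, mean = mean_v, se = se_v,
             n_unique = uniq_v, stringsAsFactors = FALSE)
}

#' The study-shaped synthetic fixture
#'
#' A complete synthetic study emulating the data shape of the motivating
#' analysis: a 17-leaf calibrated tree (human, chimp, and nine macaque
#' species of which six carry a second intra-specific sample), calibrated
#' at 6 My (Hominini), 8.5 My (crown macaques, a stand-in age) and 30 My
#' (root); autosomal families observed as exact counts only at human,
#' chimp and rhesus and missing for the other macaques; Y singletons
#' observed as unique-sequence counts at all leaves; ampliconic families
#' observed by noisy qPCR (SEs drawn from 0.05-0.5) at all leaves.
#'
#' @param seed Integer seed controlling both the evolutionary simulation
#'   and the observation noise.
#' @param n_families Named counts per category.
#' @param rates Named list: category -> named list (class ->
#'   `rate_spec`).  Defaults emulate slow autosomal turnover and fast
#'   ampliconic turnover.
#' @param root_states Named integer root copy numbers per category.
#' @param n_max State-space cap used when building the likelihood table;
#'   families whose true count anywhere exceeds it are excluded with a
#'   message, mirroring how an exceptionally amplified outlier family
#'   would be dropped from a real analysis rather than truncated.
#' @return List with `tree`, `classes`, `sim` (the `sim_dataset`),
#'   `observations` (data frame), `table` (`gene_family_table`), `n_max`,
#'   `seed`.
#' @export
study_fixture <- function(seed,
                          n_families = c(AutS = 1000, AutM = 400,
                                         YS = 16, AG = 8),
                          rates = NULL,
                          root_states = c(AutS = 1, AutM = 2, YS = 1, AG = 3),
                          n_max = 25) {
  tree <- fixture_tree()
  classes <- assign_clade_class(tree, c("Homo_sapiens", "Pan_troglodytes"),
                                "Hominini", "OWM")
  if (is.null(rates)) {
    rates <- list(
      AutS = list(Hominini = rate_spec("L", 0.004), OWM = rate_spec("L", 0.002)),
      AutM = list(Hominini = rate_spec("L", 0.008), OWM = rate_spec("L", 0.004)),
      YS   = list(Hominini = rate_spec("L_I", 0.02), OWM = rate_spec("L_I", 0.01)),
      AG   = list(Hominini = rate_spec("L", 0.13),  OWM = rate_spec("L", 0.13)))
  }
  config <- lapply(names(n_families), function(cat) {
    list(n = unname(n_families[[cat]]), rates = rates[[cat]],
         root_state = unname(root_states[[cat]]))
  })
  names(config) <- names(n_families)
  sim <- simulate_dataset(tree, classes, config, seed)
  ## outlier-exclusion precedent: families that outgrow the state space
  ## are dropped (as an exceptionally amplified family would be excluded
  ## from a real analysis), rather than silently truncated
  over <- unique(sim$truth$family[sim$truth$count > n_max])
  if (length(over)) {
    message("excluding ", length(over),
            " simulated family(ies) exceeding n_max = ", n_max)
    keep <- !(sim$truth$family %in% over)
    sim$truth <- sim$truth[keep, ]
    sim$tip_states <- sim$tip_states[setdiff(rownames(sim$tip_states), over), ,
                                     drop = FALSE]
    sim$events <- sim$events[setdiff(names(sim$events), over)]
    sim$category <- sim$category[setdiff(names(sim$category), over)]
  }
  macaques <- grep("^M_", tree$tip.label, value = TRUE)
  obs <- emulate_observations(
    sim,
    modes = c(AutS = "count", AutM = "count",
              YS = "sequence-count", AG = "qpcr"),
    qpcr_se = c(0.05, 0.5),
    mask = list(list(categories = c("AutS", "AutM"),
                     taxa = setdiff(macaques, "M_mulatta"))),
    p_detect = 1, seed = seed + 1L)
  ## a noisy qPCR mean can land just above the top state even when the true
  ## count fits; the absorbing top interval makes clamping it exact
  hi <- !is.na(obs$mean) & obs$obs_type == "qpcr" & obs$mean > n_max
  obs$mean[hi] <- n_max
  table <- observations_to_table(obs, tree$tip.label, n_max)
  list(tree = tree, classes = classes, sim = sim, observations = obs,
       table = table, n_max = n_max, seed = seed)
}

#' The fixture's 17-leaf calibrated tree
#'
#' @return An ultrametric `"phylo"` object; see [study_fixture()].
#' @export
fixture_tree <- function() {
  macaque_topo <- paste0(
    "(((M_mulatta,M_mulatta_2),(M_fascicularis,M_fascicularis_2)),",
    "((M_arctoides,M_arctoides_2),",
    "(((M_nemestrina,M_nemestrina_2),M_silenus),",
    "(((M_maura,M_maura_2),(M_tonkeana,M_tonkeana_2)),",
    "(M_ochreata,M_sylvanus)))))")
  topo <- paste0("((Homo_sapiens,Pan_troglodytes),", macaque_topo, ");")
  build_calibrated_tree(topo, list(
    list(leaves = c("Homo_sapiens", "Pan_troglodytes"), age = 6),
    list(leaves = c("M_mulatta", "M_sylvanus"), age = 8.5),
    list(leaves = c("Homo_sapiens", "M_mulatta"), age = 30)))
}

#' Write a simulated study to disk
#'
#' Emits `tree.nwk`, `classes.tsv`, `observations.tsv`, `truth.tsv`,
#' `events.tsv` and a provenance JSON (seed and configuration) under a
#' common prefix.
#'
#' @param fixture A list as returned by [study_fixture()].
#' @param prefix Output path prefix.
#' @return The written file paths, invisibly.
#' @export
write_fixture <- function(fixture, prefix) {
  paths <- paste0(prefix, c(".tree.nwk", ".classes.tsv", ".observations.tsv",
                            ".truth.tsv", ".events.tsv", ".provenance.json"))
  writeLines(write_newick(fixture$tree), paths[1])
  write_branch_classes(fixture$classes, fixture$tree, paths[2])
  write.table(fixture$observations, paths[3], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(fixture$sim$truth, paths[4], sep = "\t", quote = FALSE,
              row.names = FALSE)
  ev <- do.call(rbind, lapply(names(fixture$sim$events), function(f) {
    cbind(family = f, fixture$sim$events[[f]])
  }))
  write.table(ev, paths[5], sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(seed = fixture$seed, n_max = fixture$n_max,
         families = length(fixture$sim$category)),
    paths[6], auto_unbox = TRUE)
  invisible(paths)
}
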