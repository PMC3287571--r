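#' Benchmark scenario describing a synthetic network inference study
#'
#' Bundles the scale parameters of a benchmark: how many networks, genes,
#' time points and true edges, the hub bias of the topology generator and
#' the dynamical noise level. Two presets match the scales of published
#' GeneNetWeaver-style benchmarks: `"30x41"` (10 networks of 30 genes, 41
#' time points, 101 edges) and `"50x101"` (10 networks of 50 genes, 101
#' time points, 169 edges).
#'
#' @param preset `"30x41"`, `"50x101"`, or NULL for a custom scenario.
#' @param n_genes,n_time_points,n_networks,n_edges scenario scale.
#' @param noise_sd standard deviation of the dynamical noise.
#' @param hub_bias preferential-attachment strength of the topology
#'   generator (0 = uniform regulator choice).
#' @param seed base seed; network `i` uses `seed + i`.
#' @return A list of class `benchmark_scenario`.
#' @export
benchmark_scenario <- function(preset = NULL, n_genes = 30L, n_time_points = 41L,
                               n_networks = 10L, n_edges = NULL, noise_sd = 0.1,
                               hub_bias = 1, seed = 1L) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("30x41", "50x101"))
    if (preset == "30x41") {
      n_genes <- 30L; n_time_points <- 41L; n_networks <- 10L; n_edges <- 101L
    } else {
      n_genes <- 50L; n_time_points <- 101L; n_networks <- 10L; n_edges <- 169L
    }
  }
  if (is.null(n_edges)) n_edges <- round(3.4 * n_genes)
  stopifnot(n_genes >= 2L, n_time_points >= 2L, n_networks >= 1L,
            n_edges >= 0L, n_edges <= n_genes * (n_genes - 1L), noise_sd >= 0)
  structure(list(preset = preset, n_genes = as.integer(n_genes),
                 n_time_points = as.integer(n_time_points),
                 n_networks = as.integer(n_networks),
                 n_edges = as.integer(n_edges), noise_sd = noise_sd,
                 hub_bias = hub_bias, seed = as.integer(seed)),
            class = "benchmark_scenario")
}

#' Generate a sparse directed network with hub-biased topology
#'
#' Draws exactly `n_edges` directed edges without self-loops or duplicates.
#' Edges are added sequentially; the regulator is sampled with probability
#' proportional to `1 + hub_bias * out_degree` (preferential attachment, so
#' positive `hub_bias` concentrates outgoing edges on a few hub
#' regulators, as in transcriptional networks), and the target uniformly
#' among the remaining admissible genes. `hub_bias = 0` gives uniform
#' regulator choice.
#'
#' @param n_genes number of genes.
#' @param n_edges number of edges, `0 <= n_edges <= n_genes*(n_genes-1)`.
#' @param hub_bias non-negative preferential-attachment strength.
#' @param seed integer seed.
#' @return A [gene_network] with unit edge weights.
#' @export
generate_network <- function(n_genes, n_edges, hub_bias = 1, seed = 1L) {
  n_genes <- as.integer(n_genes); n_edges <- as.integer(n_edges)
  stopifnot(n_genes >= 1L, hub_bias >= 0)
  if (n_edges < 0L || n_edges > n_genes * (n_genes - 1L)) {
    stop(sprintf("n_edges must be in [0, %d]", n_genes * (n_genes - 1L)), call. = FALSE)
  }
  genes <- default_gene_ids(n_genes)
  set.seed(as.integer(seed))
  adj <- matrix(FALSE, n_genes, n_genes)
  diag(adj) <- TRUE   # block self-loops
  out_deg <- rep(0L, n_genes)
  reg <- integer(n_edges); tgt <- integer(n_edges)
  for (e in seq_len(n_edges)) {
    w <- 1 + hub_bias * out_deg
    w[rowSums(!adj) == 0L] <- 0   # saturated regulators
    r <- sample.int(n_genes, 1L, prob = w)
    avail <- which(!adj[r, ])
    tg <- if (length(avail) == 1L) avail else sample(avail, 1L)
    adj[r, tg] <- TRUE
    out_deg[r] <- out_deg[r] + 1L
    reg[e] <- r; tgt[e] <- tg
  }
  if (n_edges == 0L) return(gene_network(genes))
  gene_network(genes, data.frame(regulator = genes[reg], target = genes[tgt],
                                 weight = 1, stringsAsFactors = FALSE))
}

#' Simulate expression time series driven by a gene network
#'
#' Builds a gene-level transition matrix `A` whose nonzeros sit exactly on
#' the (target, regulator) positions of the network, with weights drawn as
#' random signs times Uniform(0.5, 1.5) and the whole matrix rescaled to
#' spectral radius 0.9 (guaranteeing stable, stationary dynamics). The
#' series follows \eqn{y_t = A y_{t-1} + \epsilon_t},
#' \eqn{\epsilon_t \sim N(0, noise\_sd^2 I)}, from a standard-normal (or
#' zero) start; the first `burn_in` steps are discarded.
#'
#' @param network a [gene_network].
#' @param T number of retained time points (>= 2).
#' @param noise_sd dynamical noise standard deviation (>= 0).
#' @param seed integer seed.
#' @param burn_in transient steps discarded before recording (default 50).
#' @param init `"random"` (standard normal start) or `"zero"`.
#' @return An [expression_dataset] (`n_genes` x `T`) whose gene ids match
#'   the network's.
#' @export
simulate_expressions <- function(network, T, noise_sd = 0.1, seed = 1L,
                                 burn_in = 50L, init = c("random", "zero")) {
  stopifnot(inherits(network, "gene_network"))
  T <- as.integer(T)
  if (T < 2L) stop("T must be >= 2", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  init <- match.arg(init)
  genes <- network$genes
  n <- length(genes)
  set.seed(as.integer(seed))
  A <- matrix(0, n, n)
  if (nrow(network$edges) > 0L) {
    ri <- match(network$edges$regulator, genes)
    ti <- match(network$edges$target, genes)
    w <- sample(c(-1, 1), nrow(network$edges), replace = TRUE) *
      stats::runif(nrow(network$edges), 0.5, 1.5)
    A[cbind(ti, ri)] <- w
    rho <- max(Mod(eigen(A, only.values = TRUE)$values))
    if (rho > 0) A <- A * (0.9 / rho)
  }
  y <- if (init == "random") stats::rnorm(n) else rep(0, n)
  out <- matrix(0, n, T)
  total <- burn_in + T
  for (s in seq_len(total)) {
    y <- as.numeric(A %*% y) + stats::rnorm(n, 0, noise_sd)
    if (s > burn_in) out[, s - burn_in] <- y
  }
  expression_dataset(out, gene_ids = genes)
}

#' Generate a full benchmark: paired gold standards and datasets
#'
#' Draws `n_networks` independent (network, dataset) pairs from a
#' [benchmark_scenario]; pair `i` uses seed `scenario$seed + i`, so the
#' whole benchmark is reproducible from the scenario alone.
#'
#' @param scenario a [benchmark_scenario].
#' @return A list of `n_networks` elements, each a list with `network`
#'   (gold-standard [gene_network]) and `data` ([expression_dataset]).
#' @export
make_benchmark <- function(scenario) {
  stopifnot(inherits(scenario, "benchmark_scenario"))
  lapply(seq_len(scenario$n_networks), function(i) {
    s <- scenario$seed + i
    net <- generate_network(scenario$n_genes, scenario$n_edges,
                            hub_bias = scenario$hub_bias, seed = s)
    dat <- simulate_expressions(net, scenario$n_time_points,
                                noise_sd = scenario$noise_sd, seed = s)
    list(network = net, data = dat)
  })
}
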