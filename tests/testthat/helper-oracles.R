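# Independent oracles used across tests. These deliberately avoid the
# package's own computational paths.

# Direct report-level cell counting from the raw relational tables.
count_cells <- function(srs, drug_name, pt) {
  tgt <- unique(srs$drug$primaryid[srs$drug$drugname == drug_name])
  hasev <- unique(srs$reac$primaryid[srs$reac$pt == pt])
  all_ids <- srs$demo$primaryid
  a <- sum(all_ids %in% tgt & all_ids %in% hasev)
  b <- sum(all_ids %in% tgt & !all_ids %in% hasev)
  c <- sum(!all_ids %in% tgt & all_ids %in% hasev)
  d <- length(all_ids) - a - b - c
  c(a = a, b = b, c = c, d = d)
}

# Chi-squared via expected counts: sum (O - E)^2 / E over the four cells.
chi2_expected_counts <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  N <- a + b + c + d
  O <- c(a, b, c, d)
  E <- c((a + b) * (a + c), (a + b) * (b + d),
         (c + d) * (a + c), (c + d) * (b + d)) / N
  sum((O - E)^2 / E)
}

# Quadrature oracle for the gamma-Poisson posterior: works directly on
# prior density x Poisson likelihood, no negative-binomial algebra.
ebgm_quadrature <- function(a, E, prior) {
  dens <- function(l) {
    (prior$w * dgamma(l, prior$alpha1, rate = prior$beta1) +
       (1 - prior$w) * dgamma(l, prior$alpha2, rate = prior$beta2)) *
      dpois(a, l * E)
  }
  evid <- integrate(dens, 0, Inf, rel.tol = 1e-10)$value
  elog <- integrate(function(l) log(l) * dens(l), 0, Inf,
                    rel.tol = 1e-10)$value / evid
  cdf <- function(q) integrate(dens, 0, q, rel.tol = 1e-10)$value / evid
  hi <- 1
  while (cdf(hi) < 0.05) hi <- hi * 2
  q05 <- uniroot(function(q) cdf(q) - 0.05, c(1e-12, hi),
                 tol = 1e-12)$root
  list(ebgm = exp(elog), ebgm05 = q05)
}

# Grid-search Weibull MLE over (shape, scale).
weibull_grid_mle <- function(t, shape_grid = seq(0.2, 3, by = 0.001)) {
  n <- length(t)
  lt <- log(t)
  prof <- vapply(shape_grid, function(b) {
    alpha <- mean(t^b)^(1 / b)
    n * log(b) - n * b * log(alpha) + (b - 1) * sum(lt) -
      sum((t / alpha)^b)
  }, numeric(1))
  b <- shape_grid[which.max(prof)]
  c(shape = b, scale = mean(t^b)^(1 / b))
}

# Brute-force betweenness: enumerate all shortest paths with BFS.
brute_betweenness <- function(edges, nodes, normalized = TRUE) {
  adj <- lapply(setNames(nodes, nodes), function(v) {
    unique(c(edges$gene2[edges$gene1 == v], edges$gene1[edges$gene2 == v]))
  })
  all_paths <- function(s, t) {
    # BFS distances from s
    dist <- setNames(rep(Inf, length(nodes)), nodes)
    dist[s] <- 0
    q <- s
    while (length(q)) {
      v <- q[1]; q <- q[-1]
      for (w in adj[[v]]) if (dist[w] == Inf) {
        dist[w] <- dist[v] + 1
        q <- c(q, w)
      }
    }
    if (!is.finite(dist[t])) return(list())
    paths <- list()
    grow <- function(path) {
      v <- path[length(path)]
      if (v == t) {
        paths[[length(paths) + 1L]] <<- path
        return(invisible())
      }
      for (w in adj[[v]]) if (dist[w] == dist[v] + 1 &&
                              dist[w] <= dist[t]) grow(c(path, w))
    }
    grow(s)
    paths
  }
  bc <- setNames(rep(0, length(nodes)), nodes)
  for (i in seq_along(nodes)) for (j in seq_along(nodes)) {
    if (i >= j) next
    paths <- all_paths(nodes[i], nodes[j])
    if (!length(paths)) next
    for (p in paths) {
      inner <- setdiff(p, c(nodes[i], nodes[j]))
      for (v in inner) bc[v] <- bc[v] + 1 / length(paths)
    }
  }
  n <- length(nodes)
  if (normalized && n > 2) bc <- bc / ((n - 1) * (n - 2) / 2)
  bc
}

# Exact hypergeometric upper tail by combinatorial enumeration.
hyper_tail_enum <- function(overlap, set_size, universe_size,
                            query_size) {
  ks <- overlap:min(set_size, query_size)
  sum(vapply(ks, function(k) {
    choose(set_size, k) * choose(universe_size - set_size,
                                 query_size - k)
  }, numeric(1))) / choose(universe_size, query_size)
}

# Small hand-built clean_reports object used by several modules:
# 6 reports; 2 with target drug + event X, 1 target drug only, 1 event X
# with another drug, 2 with neither.
toy_clean <- function() {
  demo <- data.frame(
    primaryid = as.character(1:6), caseid = as.character(1:6),
    fda_dt = "20230301", event_dt = "20230110", sex = "M", age = 40,
    age_cod = "YR", wt = 70, wt_cod = "KG", reporter_country = "US",
    occp_cod = "MD")
  drug <- data.frame(
    primaryid = as.character(1:6), drug_seq = 1,
    role_cod = "PS",
    drugname = c("CASPOFUNGIN", "CANCIDAS 50 MG", "CASPOFUNGIN ACETATE",
                 "MICAFUNGIN", "AMPHOTERICIN B", "FLUCONAZOLE"))
  reac <- data.frame(
    primaryid = as.character(c(1, 2, 3, 4, 5, 6)),
    pt = c("EVENT X", "EVENT X", "EVENT Y", "EVENT X", "EVENT Y",
           "EVENT Z"))
  ther <- data.frame(primaryid = as.character(1:6), drug_seq = 1,
                     start_dt = "20230101")
  as_clean_reports(srs_data(demo, drug, reac, ther))
}
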