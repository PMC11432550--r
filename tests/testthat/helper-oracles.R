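## Independent oracles used by the test suite. Each re-derives a quantity
## with a different algorithm (enumeration, closed form, textbook
## formula) so the package code path is checked against a second route.

## -- minimum spanning tree -------------------------------------------------

## Prim's algorithm, O(n^2), independent of the Kruskal-based MSN code
prim_mst_weight <- function(d) {
  n <- nrow(d)
  if (n == 1) return(0)
  in_tree <- c(TRUE, rep(FALSE, n - 1))
  best <- d[1, ]
  total <- 0
  for (step in seq_len(n - 1)) {
    cand <- which(!in_tree)
    v <- cand[which.min(best[cand])]
    total <- total + unname(best[v])
    in_tree[v] <- TRUE
    best <- pmin(best, d[v, ])
  }
  total
}

## exhaustive enumeration of all spanning trees (for small n): every
## (n-1)-subset of edges that connects all vertices
enum_mst_weight <- function(d) {
  n <- nrow(d)
  if (n == 1) return(0)
  idx <- which(upper.tri(d), arr.ind = TRUE)
  m <- nrow(idx)
  combos <- utils::combn(m, n - 1)
  best <- Inf
  for (c_i in seq_len(ncol(combos))) {
    rows <- combos[, c_i]
    comp <- seq_len(n)
    for (r in rows) {
      a <- comp[idx[r, 1]]; b <- comp[idx[r, 2]]
      comp[comp == b] <- a
    }
    if (length(unique(comp)) == 1) {
      w <- sum(d[idx[rows, , drop = FALSE]])
      if (w < best) best <- w
    }
  }
  best
}

## minimum spanning weight inside an edge subset (igraph route, used to
## measure the spanning weight of the returned MSN)
msn_spanning_weight <- function(edges, node_names) {
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges$hap_a, to = edges$hap_b, weight = edges$steps),
    directed = FALSE, vertices = data.frame(name = node_names))
  sum(igraph::E(igraph::mst(g))$weight)
}

## -- one-way ANOVA ---------------------------------------------------------

## textbook between/within sum-of-squares computation
anova_f_brute <- function(values, groups) {
  groups <- as.character(groups)
  gm <- mean(values)
  lv <- unique(groups)
  ssb <- sum(vapply(lv, function(g) {
    v <- values[groups == g]; length(v) * (mean(v) - gm)^2
  }, numeric(1)))
  ssw <- sum(vapply(lv, function(g) {
    v <- values[groups == g]; sum((v - mean(v))^2)
  }, numeric(1)))
  df1 <- length(lv) - 1
  df2 <- length(values) - length(lv)
  (ssb / df1) / (ssw / df2)
}

## -- 2x2 chi-square --------------------------------------------------------

## expected-counts formula, df = 1, no continuity correction
chi2_brute <- function(a, na, b, nb) {
  tab <- matrix(c(a, na - a, b, nb - b), nrow = 2, byrow = TRUE)
  n <- sum(tab)
  exp_tab <- outer(rowSums(tab), colSums(tab)) / n
  sum((tab - exp_tab)^2 / exp_tab)
}

## -- NG86 ------------------------------------------------------------------

## independent NG86 implementation: per-codon site fractions by direct
## enumeration of the 9 single-base changes, per-codon differences by
## explicit recursion over substitution orders
ng86_oracle <- function(a, b) {
  code <- Biostrings::GENETIC_CODE
  tr <- function(cd) unname(code[cd])
  codons <- function(s) substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
  site_counts <- function(cd) {
    s_tot <- 0; n_tot <- 0
    for (p in 1:3) {
      s <- 0; n <- 0
      for (nt in setdiff(c("A", "C", "G", "T"), substr(cd, p, p))) {
        m <- cd; substr(m, p, p) <- nt
        if (tr(m) == "*") next
        if (tr(m) == tr(cd)) s <- s + 1 else n <- n + 1
      }
      if (s + n > 0) { s_tot <- s_tot + s / (s + n); n_tot <- n_tot + n / (s + n) }
    }
    c(s_tot, n_tot)
  }
  paths <- function(from, to) {
    pos <- which(strsplit(from, "")[[1]] != strsplit(to, "")[[1]])
    if (length(pos) == 0) return(list(c(sd = 0, nd = 0)))
    out <- list()
    for (p in pos) {
      step <- from; substr(step, p, p) <- substr(to, p, p)
      if (tr(step) == "*") next
      syn <- tr(step) == tr(from)
      for (rest in paths(step, to)) {
        out[[length(out) + 1]] <- c(sd = rest[["sd"]] + as.numeric(syn),
                                    nd = rest[["nd"]] + as.numeric(!syn))
      }
    }
    out
  }
  ca <- codons(a); cb <- codons(b)
  Sa <- sum(vapply(ca, function(x) site_counts(x)[1], numeric(1)))
  Na <- sum(vapply(ca, function(x) site_counts(x)[2], numeric(1)))
  Sb <- sum(vapply(cb, function(x) site_counts(x)[1], numeric(1)))
  Nb <- sum(vapply(cb, function(x) site_counts(x)[2], numeric(1)))
  S <- (Sa + Sb) / 2; N <- (Na + Nb) / 2
  Sd <- 0; Nd <- 0
  for (i in seq_along(ca)) {
    if (ca[i] == cb[i]) next
    pc <- paths(ca[i], cb[i])
    if (length(pc) == 0) {
      ## all pathways blocked by a stop: fall back to counting every order
      pos <- which(strsplit(ca[i], "")[[1]] != strsplit(cb[i], "")[[1]])
      perms <- if (length(pos) == 1) list(pos) else {
        do.call(c, lapply(seq_along(pos), function(k) {
          lapply(combinat_perm(pos[-k]), function(r) c(pos[k], r))
        }))
      }
      acc <- t(vapply(perms, function(ord) {
        cur <- ca[i]; sdv <- 0; ndv <- 0
        for (p in ord) {
          nxt <- cur; substr(nxt, p, p) <- substr(cb[i], p, p)
          if (tr(nxt) != "*" && tr(cur) != "*" && tr(cur) == tr(nxt)) sdv <- sdv + 1
          else ndv <- ndv + 1
          cur <- nxt
        }
        c(sdv, ndv)
      }, numeric(2)))
      Sd <- Sd + mean(acc[, 1]); Nd <- Nd + mean(acc[, 2])
    } else {
      m <- do.call(rbind, pc)
      Sd <- Sd + mean(m[, "sd"]); Nd <- Nd + mean(m[, "nd"])
    }
  }
  pS <- Sd / S; pN <- Nd / N
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  list(S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
       Ks = jc(pS), Ka = jc(pN))
}

combinat_perm <- function(x) {
  if (length(x) <= 1) return(list(x))
  do.call(c, lapply(seq_along(x), function(i) {
    lapply(combinat_perm(x[-i]), function(r) c(x[i], r))
  }))
}

## random sense-codon sequence without internal stops, for oracle tests
random_cds <- function(n_codons) {
  sense <- setdiff(names(Biostrings::GENETIC_CODE),
                   c("TAA", "TAG", "TGA"))
  paste0(sample(sense, n_codons, replace = TRUE), collapse = "")
}

## mutate a CDS at a few random positions, avoiding stop codons
mutate_cds <- function(cds, n_mut) {
  v <- strsplit(cds, "")[[1]]
  for (k in seq_len(n_mut)) {
    repeat {
      p <- sample(length(v), 1)
      old <- v[p]
      v[p] <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
      s <- paste0(v, collapse = "")
      cods <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
      if (!any(cods %in% c("TAA", "TAG", "TGA"))) break
      v[p] <- old
    }
  }
  paste0(v, collapse = "")
}
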