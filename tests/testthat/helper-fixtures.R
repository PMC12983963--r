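# Shared fixtures: the two scoring panels' judgment matrices, the
# worked-example weights and membership matrices, and small independent
# oracles used across tests.

expert_matrices <- function() {
  list(
    first_level = judgment_matrix(c(4, 3, 2),
      labels = c("environmental", "physiological", "behavioral")
    ),
    environmental = judgment_matrix(c(2, 5, 3), labels = c("b11", "b12", "b13")),
    physiological = judgment_matrix(c(2, 3, 3, 2, 3, 2), labels = paste0("b2", 1:4)),
    behavioral = judgment_matrix(c(2, 2, 2, 3, 4, 2), labels = paste0("b3", 1:4))
  )
}

farmer_matrices <- function() {
  list(
    first_level = judgment_matrix(c(2, 4, 4),
      labels = c("environmental", "physiological", "behavioral")
    ),
    environmental = judgment_matrix(c(5, 7, 3), labels = c("b11", "b12", "b13")),
    physiological = judgment_matrix(c(3, 5, 2, 2, 3, 3), labels = paste0("b2", 1:4)),
    behavioral = judgment_matrix(c(3, 3, 4, 2, 3, 2), labels = paste0("b3", 1:4))
  )
}

expert_hierarchy <- function() {
  m <- expert_matrices()
  hierarchy_model(m$first_level, m[-1])
}

# Worked-example inputs: global indicator weights, expert-scored membership
# matrices, and the first-level weight triple.
worked_example <- function() {
  list(
    w1 = c(0.39, 0.11, 0.05),
    w2 = c(0.14, 0.05, 0.03, 0.13),
    w3 = c(0.06, 0.03, 0.02, 0.01),
    w_first = c(0.54, 0.35, 0.11),
    e1 = membership_matrix(rbind(
      c(0, 1, 0, 0, 0), c(0, 0.9, 0.1, 0, 0), c(1, 0, 0, 0, 0)
    )),
    e2 = membership_matrix(rbind(
      c(1, 0, 0, 0, 0), c(0.8, 0.2, 0, 0, 0), c(0.7, 0.3, 0, 0, 0), c(1, 0, 0, 0, 0)
    )),
    e3 = membership_matrix(rbind(
      c(0.8, 0.2, 0, 0, 0), c(0.9, 0.1, 0, 0, 0), c(0.6, 0.4, 0, 0, 0), c(1, 0, 0, 0, 0)
    ))
  )
}

worked_example_model <- function() {
  wx <- worked_example()
  fce_model(
    wx$w_first,
    list(environmental = wx$w1, physiological = wx$w2, behavioral = wx$w3),
    membership = list(
      environmental = wx$e1, physiological = wx$e2, behavioral = wx$e3
    ),
    mode = "global"
  )
}

# Build a perfectly consistent judgment matrix a_ij = w_i / w_j from a
# positive weight vector (oracle for weight recovery).
consistent_matrix <- function(w, labels = NULL) {
  m <- outer(w, w, "/")
  diag(m) <- 1
  as_judgment_matrix(m, labels = labels)
}

# O(n^2) brute-force Kendall oracle: explicit concordant/discordant pair
# counting with tie correction, independent of the package implementation.
kendall_brute_force <- function(x, y) {
  n <- length(x)
  conc <- 0
  disc <- 0
  tx <- 0
  ty <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      dx <- x[i] - x[j]
      dy <- y[i] - y[j]
      if (dx == 0 && dy == 0) {
        tx <- tx + 1
        ty <- ty + 1
      } else if (dx == 0) {
        tx <- tx + 1
      } else if (dy == 0) {
        ty <- ty + 1
      } else if (dx * dy > 0) {
        conc <- conc + 1
      } else {
        disc <- disc + 1
      }
    }
  }
  n0 <- n * (n - 1) / 2
  (conc - disc) / sqrt((n0 - tx) * (n0 - ty))
}

random_saaty_upper <- function(n) {
  vals <- c(1:9, 1 / (2:9))
  sample(vals, n * (n - 1) / 2, replace = TRUE)
}
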