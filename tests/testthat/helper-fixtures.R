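# Shared fixtures: a default RTI source, free-medium parameters, and an
# independent finite-difference solver for the radial diffusion equation with
# linear uptake. The FD solver is deliberately written from scratch (uniform
# grid, its own discretisation) so it can act as an oracle for the package's
# closed-form forward model.

default_source <- function(...) {
  ionto_source(transport_number = 0.3, free_D = 1.24e-5, ...)
}

free_medium <- function() ecs_params(1, 1, 0)

# Radial diffusion + linear uptake with a rectangular release pulse from a
# small sphere of radius `a`, solved on a uniform grid by the classic
# three-point stencil in u = r*C (which linearises the spherical Laplacian).
# Returns a function C(r, t) interpolating the solution.
fd_reference_solution <- function(source, ecs, a = 0.25, dr = 0.25,
                                  r_max = 900, t_max = 60,
                                  nt_out = 241) {
  Dstar <- source$free_D / ecs$lambda^2 * 1e8           # um^2/s
  Q <- source$step_current * 1e-9 * source$transport_number / 96485 * 1e21
  r <- seq(a, r_max, by = dr)
  n <- length(r)
  u0 <- numeric(n)                                       # u = r * C
  flux <- Q / (4 * pi * a^2 * ecs$alpha)                 # -D* dC/dr at r = a
  rhs <- function(t, u, p) {
    C <- u / r
    # interior second difference of u
    d2 <- c(0, diff(diff(u)) / dr^2, 0)
    du <- Dstar * d2 - ecs$kprime * u
    # inner boundary: ghost node from -D*(u'/r - u/r^2) = flux * on(t)
    on <- if (t <= source$pulse_duration) 1 else 0
    uprime_a <- u[1] / a - on * flux * a / Dstar
    ghost_in <- u[1] - dr * uprime_a +
      dr^2 / 2 * ((ecs$kprime / Dstar) * u[1])
    du[1] <- Dstar * (u[2] - 2 * u[1] + ghost_in) / dr^2 - ecs$kprime * u[1]
    du[n] <- 0                                           # far Dirichlet u = 0
    list(du)
  }
  times <- seq(0, t_max, length.out = nt_out)
  brk <- source$pulse_duration
  t1 <- times[times <= brk]
  t2 <- times[times > brk]
  sol1 <- deSolve::lsoda(u0, unique(c(t1, brk)), rhs, parms = NULL,
                         rtol = 1e-9, atol = 1e-9,
                         jactype = "bandint", bandup = 1, banddown = 1)
  u_brk <- sol1[nrow(sol1), -1]
  sol2 <- deSolve::lsoda(u_brk, c(brk, t2), rhs, parms = NULL,
                         rtol = 1e-9, atol = 1e-9,
                         jactype = "bandint", bandup = 1, banddown = 1)
  tt <- c(sol1[sol1[, 1] %in% t1, 1], sol2[-1, 1])
  uu <- rbind(sol1[sol1[, 1] %in% t1, -1, drop = FALSE],
              sol2[-1, -1, drop = FALSE])
  function(r_q, t_q) {
    ui <- apply(uu, 1, function(row) stats::approx(r, row, xout = r_q)$y)
    stats::approx(tt, ui, xout = t_q)$y / r_q
  }
}

# Parameter table for a null two-group cohort (no real group difference
# unless delta_lambda shifts one group), in the shape compare_groups expects.
null_param_table <- function(seed, delta_lambda = 0) {
  set.seed(seed)
  layers <- c("III", "IV", "V", "VI")
  expand <- expand.grid(group = c("control", "etoh"), animal = 1:6,
                        layer = layers, stringsAsFactors = FALSE)
  expand$animal_id <- paste(expand$group, expand$animal, sep = "_")
  expand$alpha <- stats::rnorm(nrow(expand), 0.2, 0.01)
  expand$lambda <- stats::rnorm(nrow(expand), 1.5, 0.03) +
    ifelse(expand$group == "etoh", delta_lambda, 0)
  expand
}

# Brute-force two-way ANOVA sums of squares for a balanced table with
# factors A, B and replicate values y (textbook partitioning).
brute_force_anova <- function(df) {
  g <- mean(df$y)
  a_means <- tapply(df$y, df$A, mean)
  b_means <- tapply(df$y, df$B, mean)
  cell_means <- tapply(df$y, interaction(df$A, df$B), mean)
  n_a <- table(df$A)[1]; n_b <- table(df$B)[1]
  n_cell <- table(interaction(df$A, df$B))[1]
  ss_a <- sum(table(df$A) * (a_means - g)^2)
  ss_b <- sum(table(df$B) * (b_means - g)^2)
  ss_cells <- sum(table(interaction(df$A, df$B)) * (cell_means - g)^2)
  ss_ab <- ss_cells - ss_a - ss_b
  ss_tot <- sum((df$y - g)^2)
  ss_err <- ss_tot - ss_cells
  df_a <- nlevels(factor(df$A)) - 1
  df_b <- nlevels(factor(df$B)) - 1
  df_ab <- df_a * df_b
  df_err <- nrow(df) - nlevels(interaction(df$A, df$B))
  list(F_a = (ss_a / df_a) / (ss_err / df_err),
       F_b = (ss_b / df_b) / (ss_err / df_err),
       F_ab = (ss_ab / df_ab) / (ss_err / df_err),
       ss = c(A = ss_a, B = ss_b, AB = ss_ab, err = ss_err, tot = ss_tot))
}
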