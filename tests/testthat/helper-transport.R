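# Exact balanced-transport linear program solved by an external oracle
# (scipy.optimize.linprog), used to check the eps -> 0, gamma -> Inf limit
# of the entropic unbalanced cost on small instances.

lp_transport_cost <- function(a, b, C) {
  stopifnot(length(a) == nrow(C), length(b) == ncol(C),
            abs(sum(a) - sum(b)) < 1e-12)
  payload <- jsonlite::toJSON(list(a = a, b = b, C = C), digits = NA)
  script <- '
import sys, json
import numpy as np
from scipy.optimize import linprog
d = json.load(sys.stdin)
a = np.asarray(d["a"], float); b = np.asarray(d["b"], float)
C = np.asarray(d["C"], float)
n, m = C.shape
A_eq = []
for i in range(n):
    row = np.zeros((n, m)); row[i, :] = 1
    A_eq.append(row.ravel())
for j in range(m):
    col = np.zeros((n, m)); col[:, j] = 1
    A_eq.append(col.ravel())
res = linprog(C.ravel(), A_eq=np.asarray(A_eq),
              b_eq=np.concatenate([a, b]), bounds=(0, None),
              method="highs")
print(json.dumps({"cost": res.fun, "ok": bool(res.success)}))
'
  f <- tempfile(fileext = ".py")
  writeLines(script, f)
  on.exit(unlink(f))
  out <- system2("python3", f, stdout = TRUE, input = as.character(payload))
  res <- jsonlite::fromJSON(paste(out, collapse = ""))
  if (!isTRUE(res$ok)) stop("transport LP oracle failed")
  res$cost
}

has_lp_oracle <- function() {
  nzchar(Sys.which("python3"))
}
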