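# rwdsandbox

Hospitals hold the clinical data that modern observational research and
personalised-medicine work need, but privacy law (GDPR, HIPAA) and data
ownership mean they cannot simply hand tables to external researchers.
Distributed analytics resolves the tension by inverting the flow: the
analysis travels to the data, runs inside the hospital's trust zone, and
only aggregate results come back out.

`rwdsandbox` implements a complete, self-contained sandbox platform of this
kind as an R package, for infrastructure teams and methods researchers who
want a working, testable reference of the whole pipeline:

- **Job protocol** — an external client publishes requests as XML files (a
  Message Master Table plus one `job_<jobID>.xml` detail file per job) on a
  channel the proxy *polls*; nothing outside the hospital ever initiates a
  connection inward, and all responses are status messages
  (`info.assigned.proc`, `info.status.job`, `error.*`) and result artefacts.
- **Tokens** — each task travels as a zip archive containing a descriptor
  XML plus the data payload and/or script, treated as a black box by the
  executor.
- **Processor** — watches input folders, atomically claims tokens, runs
  scripts (R / Python / shell) or locally loaded container images in
  background subprocesses with per-job logs, and deposits an output token;
  remote image pulls are refused by design.
- **Proxy** — the only component touching both sides: permission checks,
  certified datamart/algorithm catalogs, cohort queries, token preparation,
  least-ongoing load balancing across processors, and result routing.
- **permAgent** — identity and access management: users, group/subgroup
  hierarchies, item grants, ticketed sessions with TTL, fail-closed checks.
- **Notary** — every request and result hash is stored off-chain and
  appended to a SHA-256 hash-chained append-only ledger (proof of
  existence, tamper evidence); results pass a dual Ed25519 signature
  workflow — sandbox signs, user verifies and countersigns — after which
  exactly three report artefacts (initial, sandbox-signed, countersigned)
  are notarised and the result is officially issued.
- **Scheduler** — periodic task list with freeze/resume/remove and
  exactly-once firing per due instant.
- **Fixtures** — deterministic synthetic datamarts (including a minimal
  OMOP-style person/condition pair), a conjunctive cohort-query engine, and
  toy aggregate-only algorithms, so everything runs with zero downloads.

## Worked example

```r
library(rwdsandbox)

sb <- sandbox_local(tempfile("sandbox-"), users = c(alice = "pw"))
s  <- sb$login("alice", "pw")

sb$submit(job_request("j1", s$ticket, "alice",
                      datamart = "patients", algorithm = "row_counter",
                      query = cohort_query(pred("age", ">=", 60)),
                      sign = TRUE))
sb$run()

sb$channel$read_status()[, c("code", "payload")]
#>                 code                                        payload
#> 1    info.status.job                                         queued
#> 2 info.assigned.proc                                         proc01
#> 3    info.status.job                                        running
#> 4    info.status.job done: result signed, awaiting countersignature

rawToChar(sb$channel$artefact("j1", "row_count.txt"))
#> [1] "59\n"

sb$countersign("j1", "alice")
sb$notary$report_state("j1")   # "countersigned"
sb$notary$ledger_length()      # 5  (1 request + 1 result + 3 reports)
sb$notary$verify_ledger()$ok   # TRUE
```

The submitted cohort (`age >= 60` over the 100-row demo patient datamart)
contains 59 patients; the only bytes that ever reach the channel are that
aggregate count, the status messages and the signed report envelope — never
a data row. The five ledger entries are the job's full accountability
chain, and `verify_ledger()` recomputes every hash link.

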