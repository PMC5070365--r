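# Bundled example data

`county_zone_counts.csv` — per-band district and inhabitant counts of a
published accessibility zone tabulation for a rural county of 464 analysed
districts and 239,102 inhabitants (car travel time to the nearest GP in
5-minute bands; public-transport round-trip time to the nearest GP in
1-hour bands plus a no-connection row). Used by the worked examples to
recompute the table's share arithmetic from raw counts. In the source
table the public-transport district column is internally inconsistent by
one district (rows sum to 465 against a printed total of 464); counts are
stored as printed, and only inhabitant-based shares are used in the
examples.
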