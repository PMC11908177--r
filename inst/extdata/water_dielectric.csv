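"temperature","epsilon"
273.15,87.74
276.15,86.548
279.15,85.373
282.15,84.214
285.15,83.072
288.15,81.945
291.15,80.835
294.15,79.74
297.15,78.66
300.15,77.595
303.15,76.545
306.15,75.51
309.15,74.489
312.15,73.483
315.15,72.49
318.15,71.511
321.15,70.546
324.15,69.593
327.15,68.654
330.15,67.728
333.15,66.814
336.15,65.912
339.15,65.023
342.15,64.146
345.15,63.28
348.15,62.426
351.15,61.582
354.15,60.75
357.15,59.929
360.15,59.118
363.15,58.317
366.15,57.527
369.15,56.746
372.15,55.975
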