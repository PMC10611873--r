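quantity,numerator,denominator,value
sjl_n,145,934,NA
males_in_sjl,57,145,NA
males_in_no_sjl,201,789,NA
females_total,676,934,NA
short_sleepers,31,934,NA
average_sleepers,764,934,NA
long_sleepers,139,934,NA
sleep_duration_weekday_h,NA,NA,8.1
sleep_duration_weekend_h,NA,NA,8.7
mid_sleep_difference_mean_h,NA,NA,0.83
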